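# Acquisition protocol: closures per object/stiffness/control-signal.
protocol:
  - {n_closures: 10, object_name: "Void",       stiffness_label: void,  control_signal: sinusoidal}
  - {n_closures: 10, object_name: "Hand dynam", stiffness_label: rigid, control_signal: sinusoidal}
  - {n_closures: 10, object_name: "Hand dynam", stiffness_label: rigid, control_signal: emg}
  - {n_closures: 5,  object_name: "4xS1",       stiffness_label: soft,  control_signal: sinusoidal}
  - {n_closures: 5,  object_name: "4xS1",       stiffness_label: soft,  control_signal: emg}
  - {n_closures: 5,  object_name: "2xS1",       stiffness_label: soft,  control_signal: sinusoidal}
  - {n_closures: 5,  object_name: "2xS1",       stiffness_label: soft,  control_signal: emg}
  - {n_closures: 5,  object_name: "4xS2",       stiffness_label: rigid, control_signal: sinusoidal}
  - {n_closures: 5,  object_name: "4xS2",       stiffness_label: rigid, control_signal: emg}
  - {n_closures: 5,  object_name: "4xS3",       stiffness_label: rigid, control_signal: sinusoidal}
  - {n_closures: 5,  object_name: "4xS3",       stiffness_label: rigid, control_signal: emg}
  - {n_closures: 5,  object_name: "2xS1-2xS4",  stiffness_label: soft,  control_signal: sinusoidal}
  - {n_closures: 5,  object_name: "2xS1-2xS4",  stiffness_label: soft,  control_signal: emg}
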