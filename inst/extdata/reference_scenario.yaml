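# Reference banana voyage: warm loading, 14-day cooled ocean transport,
# 12-hour harbor gap, 4 days of artificial ripening. All values are
# synthetic study conditions.
shipment_ids: ["4711"]
t_packing: 0
t_transport: 6
t_harbor: 342
t_ripening: 354
t_end: 450
T_load: 26
setpoint: 13.2
true_k_M: 0.05
ripening_q: 0.3
ambient: 18
harbor_k: 0.02
supply_noise: 0.05
box_noise: 0.05
sampling: 1
seed: 1
queries:
  - at: 102
  - at: 150
    setpoint_delta: -0.5
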