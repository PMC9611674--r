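# Minimal configuration fragment: wiring of the ripening model alone,
# as it appears in a cargo-type configuration (the full banana chain is
# in banana_config.yaml).
Bananas:
  RipeningModel:
    Topic_In: Transports_Shipment_#ID_CoolPara
    Topic_Out: Transports_Shipment_#ID_RipePara
    LifeCycleTranslate:
      Start_Transport: Start_Collect
      Arrive_Transport: Stop_Collect
      Start_Ripening: Start_Model
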