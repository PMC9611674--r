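# Cargo-type configuration for the banana cool chain.
# Topic patterns contain the literal token #ID, replaced by the shipment
# number at instantiation time; document order of the models defines the
# enriched-stream chain order.
Bananas:
  CoolIdentModel:
    Topic_In: Transports_Shipment_#ID_Sensors
    Topic_Out: Transports_Shipment_#ID_CoolPara
    LifeCycleTranslate:
      Start_Transport: Start_Model
      Arrive_Transport: Stop_Model
  RipeningModel:
    Topic_In: Transports_Shipment_#ID_CoolPara
    Topic_Out: Transports_Shipment_#ID_RipePara
    LifeCycleTranslate:
      Start_Transport: Start_Collect
      Arrive_Transport: Stop_Collect
      Start_Ripening: Start_Model
      Stop_Ripening: Stop_Model
  CoolPredictModel:
    Topic_In: Transports_Shipment_#ID_RipePara
    Topic_Out: Transports_Shipment_#ID_TempPred
    LifeCycleTranslate:
      Start_Transport: Start_Model
      Arrive_Transport: Stop_Model
  GreenLifeModel:
    Topic_In: Transports_Shipment_#ID_TempPred
    Topic_Out: Transports_Shipment_#ID_GreenLife
    LifeCycleTranslate:
      Start_Transport: Start_Model
      Stop_Ripening: Stop_Model
models:
  CoolIdentModel:
    stable_hours: 72
    spread_tol: 0.02
    window: 24
  RipeningModel:
    smooth_window: 5
  CoolPredictModel:
    supply_window: 24
    chilling_floor: 12.5
  GreenLifeModel:
    GL0: 28
    Q10: 3
    T_ref: 13
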