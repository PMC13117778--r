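{
  "haar": {
    "orthogonal": [true],
    "dec_lo": [0.707106781186548, 0.707106781186548],
    "dec_hi": [-0.707106781186548, 0.707106781186548]
  },
  "db2": {
    "orthogonal": [true],
    "dec_lo": [-0.12940952255126, 0.224143868042013, 0.836516303737808, 0.482962913144534],
    "dec_hi": [-0.482962913144534, 0.836516303737808, -0.224143868042013, -0.12940952255126]
  },
  "db4": {
    "orthogonal": [true],
    "dec_lo": [-0.010597401785069, 0.0328830116668852, 0.0308413818355608, -0.187034811719093, -0.0279837694168599, 0.630880767929859, 0.714846570552916, 0.230377813308897],
    "dec_hi": [-0.230377813308897, 0.714846570552916, -0.630880767929859, -0.0279837694168599, 0.187034811719093, 0.0308413818355608, -0.0328830116668852, -0.010597401785069]
  },
  "sym4": {
    "orthogonal": [true],
    "dec_lo": [-0.0757657147892733, -0.0296355276459985, 0.497618667632015, 0.803738751805916, 0.297857795605277, -0.0992195435768472, -0.0126039672620378, 0.0322231006040427],
    "dec_hi": [-0.0322231006040427, -0.0126039672620378, 0.0992195435768472, 0.297857795605277, -0.803738751805916, 0.497618667632015, 0.0296355276459985, -0.0757657147892733]
  },
  "coif2": {
    "orthogonal": [true],
    "dec_lo": [-0.000720549445520347, -0.00182320887091103, 0.00561143481936883, 0.0236801719468478, -0.0594344186464311, -0.0764885990782808, 0.417005184423239, 0.812723635449414, 0.386110066822763, -0.0673725547237256, -0.0414649367868718, 0.0163873364632036],
    "dec_hi": [-0.0163873364632036, -0.0414649367868718, 0.0673725547237256, 0.386110066822763, -0.812723635449414, 0.417005184423239, 0.0764885990782808, -0.0594344186464311, -0.0236801719468478, 0.00561143481936883, 0.00182320887091103, -0.000720549445520347]
  },
  "coif3": {
    "orthogonal": [true],
    "dec_lo": [-3.45997731972728e-05, -7.0983302506379e-05, 0.000466216959820403, 0.00111751877083063, -0.0025745176881368, -0.00900797613673062, 0.0158805448636694, 0.0345550275732977, -0.0823019271062998, -0.0717998216191548, 0.42848347637737, 0.793777222626087, 0.405176902409118, -0.0611233900029726, -0.0657719112814694, 0.0234526961420772, 0.00778259642567275, -0.0037935128643808],
    "dec_hi": [0.0037935128643808, 0.00778259642567275, -0.0234526961420772, -0.0657719112814694, 0.0611233900029726, 0.405176902409118, -0.793777222626087, 0.42848347637737, 0.0717998216191548, -0.0823019271062998, -0.0345550275732977, 0.0158805448636694, 0.00900797613673062, -0.0025745176881368, -0.00111751877083063, 0.000466216959820403, 7.0983302506379e-05, -3.45997731972728e-05]
  },
  "bior3.5": {
    "orthogonal": [false],
    "dec_lo": [-0.0138106793200498, 0.0414320379601493, 0.0524805814161891, -0.267927178808965, -0.0718155324642587, 0.966747552403483, 0.966747552403483, -0.0718155324642587, -0.267927178808965, 0.0524805814161891, 0.0414320379601493, -0.0138106793200498],
    "dec_hi": [0, 0, 0, 0, -0.176776695296637, 0.530330085889911, -0.530330085889911, 0.176776695296637, 0, 0, 0, 0]
  }
}
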