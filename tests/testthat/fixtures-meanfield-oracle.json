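[
  {
    "params": {
      "T": 19,
      "b_e": 60,
      "E_L_e": -64,
      "E_L_i": -64
    },
    "states_khz": [
      [0.0554499588441104, 0.0129379553254694, 0.000440349586424418, 0.000162873189430684, 0.000240882767946459, 61.1137784086168, 0],
      [0.000103662582114339, 0.190969845093787, 6.1608100659214e-05, 0.000140416746772826, 0.000165305497241206, 204.110216279514, 0],
      [0.102121674595401, 0.0172991782426834, 8.75564613379538e-05, 9.35949970968067e-05, 7.88301244610921e-05, 109.136408404447, 0],
      [0.00280958167277277, 0.0579950018320233, 0.000220375135890208, 2.9474288597703e-05, 0.000240067026694305, 105.104515026323, 0]
    ],
    "coupling_khz": [0, 0.002, 0.005, 0.02],
    "derivs_khz": [
      [0.00591488428904453, 0.00815235815843806, 0.00061827505635082, 0.00089905955083795, 0.00123690796157535, 3.20476997382939, 0],
      [-5.45592537443889e-06, -0.0100510444786204, -6.48449765197355e-06, -1.37387929630134e-05, 0.00190204582845593, -0.402000677632168, 0],
      [0.00413597252289398, 0.00860031443619725, 0.000315652811050931, 0.000665992905482577, 0.00139643815689222, 5.90902765891517, 0],
      [-0.00014626062252146, -0.00283453764455337, -2.27902140748346e-05, 4.76498337824224e-06, 0.000127373579930773, -0.0416341296862798, 0]
    ]
  },
  {
    "params": {
      "T": 5,
      "b_e": 120,
      "E_L_e": -80,
      "E_L_i": -78.667
    },
    "states_khz": [
      [0.0608553670812398, 0.168646206473932, 0.00020861999259796, -1.05286405421793e-05, 0.000210397385759279, 66.7383758816868, 0],
      [0.0949477816931903, 0.144662909721956, 0.000186312494683079, 0.000143255923315883, 8.7456330889836e-05, 108.105853898451, 0],
      [0.198705154377967, 0.123033611243591, 0.000484211027156562, -2.58592984639108e-05, 0.000309062820510007, 159.79844906833, 0],
      [0.104130772408098, 0.147834264254197, 0.000303704057470895, -0.000167092160880566, 0.000185777788632549, 238.940859236754, 0]
    ],
    "coupling_khz": [0.001, 0, 0.01, 0.03],
    "derivs_khz": [
      [-0.012171073416239, -0.0337273533253246, 0.00065722714347822, 0.00205670180049287, 0.00560351282252288, 7.1691672979854, 0],
      [-0.0120519859125706, 0.00803152899466599, 0.000652055466299585, -0.000541168515449477, 0.000287866945304542, 11.1775220953859, 0],
      [-0.00136753478129674, 0.0137667738451381, -0.000184290055046919, -8.37855460290634e-05, 0.000824153518971356, 23.5250216272194, 0],
      [0.0169515728731339, 0.00848663590830188, 0.00131540989165116, 0.000786175679479172, 0.000285988834472225, 12.0178109704983, 0]
    ]
  },
  {
    "params": {
      "T": 40,
      "b_e": 0,
      "E_L_e": -60,
      "E_L_i": -80
    },
    "states_khz": [
      [0.0891880958341062, 0.168776287976652, 7.75848003104329e-06, -0.000109979517944157, 0.000387374436482787, 169.93579713162, 0],
      [0.0789300621952862, 0.103469923324883, 5.89955809991807e-05, -6.30455107428133e-05, 0.000193596492288634, 12.82024809625, 0],
      [0.0967457749415189, 0.087425000872463, 0.000345492949476466, 0.000112755177915096, 6.78825349314138e-05, 146.495775994845, 0],
      [0.183775191474706, 0.0686396431643516, 0.000130242842365988, 0.0001372986741364, 0.000450178788159974, 105.366966454312, 0]
    ],
    "coupling_khz": [0, 0.004, 0.001, 0.05],
    "derivs_khz": [
      [-0.00222645648048501, -0.00207206886774698, 0.000197896642936927, 0.000189964565728812, 0.000152165939940659, -0.33987159426324, 0],
      [0.0021345999730395, 0.00205327724726234, 0.00017925974613401, 0.000178479576229972, 0.000158585665528405, -0.0256404961925, 0],
      [0.00222511382443038, 0.00245837977156075, 0.000180679024698384, 0.000213170417024088, 0.000237978476674262, -0.29299155198969, 0],
      [0.00018891909615581, 0.00306730780385401, -5.18363236154604e-06, 1.63145205075171e-05, 0.00035342906172167, -0.210733932908624, 0]
    ]
  }
]
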