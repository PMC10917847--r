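{
  "comment": "Second-order effective-threshold polynomial coefficients (Volts) for the AdEx mean-field transfer function, per population, as fitted in the public semi-analytical derivation. Order: P0, P_muV, P_sigmaV, P_tauVN, P_muV2, P_sigmaV2, P_tauVN2, P_muV.sigmaV, P_muV.tauVN, P_sigmaV.tauVN.",
  "excitatory": [-0.04983106, 0.005063550882777035, -0.023470121807314552,
                 0.0022951513725067503, -0.0004105302652029825,
                 0.010547051343547399, -0.03659252821136933,
                 0.007437487505797858, 0.001265064721846073,
                 -0.04072161294490446],
  "inhibitory": [-0.05149122024209484, 0.004003689190271077,
                 -0.008352013668528155, 0.0002414237992765705,
                 -0.0005070645080016026, 0.0014345394104282397,
                 -0.014686689498949967, 0.004502706285435741,
                 0.0028472190352532454, -0.015357804594594548]
}
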