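# Internal coefficient tables for the numerically stable evaluation of the
# exact MSD. Machine-generated from exact rational series coefficients of the
# closed-form MSD; do not edit by hand.

# Small-time expansion: msd/eta^2 = sum_{k=4}^{18} tau^k * P_k(zeta),
# P_k a polynomial in zeta of degree k - 4 (coefficients low -> high).
.msd_tau_series <- list(
  c(0.25),
  c(-0.06666666666666667, -0.16666666666666666),
  c(0.013888888888888888, 0.041666666666666664, 0.06944444444444445),
  c(-0.002380952380952381, -0.008333333333333333, -0.01626984126984127, -0.022222222222222223),
  c(0.00034722222222222224, 0.001388888888888889, 0.003125, 0.004861111111111111, 0.005902777777777778),
  c(-4.409171075837743e-05, -0.0001984126984126984, -0.0005070546737213404, -0.0008928571428571428, -0.0012014991181657849, -0.001355820105820106),
  c(4.96031746031746e-06, 2.48015873015873e-05, 7.10978835978836e-05, 0.00014054232804232804, 0.0002099867724867725, 0.00025628306878306876, 0.0002761243386243386),
  c(-5.010421677088344e-07, -2.7557319223985893e-06, -8.768237934904602e-06, -1.9290123456790123e-05, -3.191638608305275e-05, -4.243827160493827e-05, -4.8450777617444285e-05, -5.070546737213404e-05),
  c(4.592886537330982e-08, 2.755731922398589e-07, 9.645061728395062e-07, 2.3423721340388006e-06, 4.2713844797178134e-06, 6.200396825396825e-06, 7.57826278659612e-06, 8.267195767195768e-06, 8.496840094062317e-06),
  c(-3.854170520837187e-09, -2.505210838544172e-08, -9.571190126745682e-08, -2.5469643525199083e-07, -5.090716896272452e-07, -8.058428197317086e-07, -1.060218074106963e-06, -1.219202608091497e-06, -1.289862400973512e-06, -1.3110603388381166e-06),
  c(2.9823938554097286e-10, 2.08767569878681e-09, 8.648942180688213e-09, 2.505210838544172e-08, 5.457780755399803e-08, 9.394540644540644e-08, 1.3331300533681486e-07, 1.6283870450537117e-07, 1.7924187071012467e-07, 1.8580313719202608e-07, 1.8759257350527193e-07),
  c(-2.1412058449095486e-11, -1.6059043836821613e-10, -7.173039580446987e-10, -2.248266137155026e-09, -5.31019049537568e-09, -9.903077032706663e-09, -1.5152090218227783e-08, -1.9744976755558767e-08, -2.280690111377942e-08, -2.4337863292889748e-08, -2.489457681256623e-08, -2.503375519248535e-08),
  c(1.4338431997162156e-12, 1.1470745597729725e-11, 5.496398932245493e-11, 1.8544372049663054e-10, 4.724991290798169e-10, 9.50924810051794e-10, 1.5660435427300506e-09, 2.1811622754083074e-09, 2.6595879563802844e-09, 2.946643364963471e-09, 3.0771230961376464e-09, 3.1206163398623718e-09, 3.1306532422603853e-09),
  c(-8.996663213905666e-14, -7.647163731819816e-13, -3.913548498048965e-12, -1.414725290386666e-11, -3.870814347782913e-11, -8.3736442863427e-11, -1.480625848428525e-10, -2.204294945697062e-10, -2.847556365491317e-10, -3.297839359347296e-10, -3.5434482650869206e-10, -3.6457853091450975e-10, -3.6772736303937673e-10, -3.6840211278041965e-10),
  c(5.310530369319317e-15, 4.779477332387385e-14, 2.602159880966465e-13, 1.0036902398013508e-12, 2.936723294233582e-12, 6.8027894030980454e-12, 1.2878036145599343e-11, 2.0472094573725967e-11, 2.806615300185259e-11, 3.414139974435389e-11, 3.800746585321835e-11, 3.994049890765058e-11, 4.0683973159355286e-11, 4.089639437412806e-11, 4.093887861708261e-11)
)

# Low-drag expansion: msd/eta^2 = sum_{k=0}^{10} zeta^k * [A_k(tau) + B_k(tau) e^-tau],
# A_k, B_k polynomials in tau (coefficients high -> low, Horner order).
.msd_zeta_series_a <- list(
  c(0.6666666666666666, -1.0, 0.0, 2.0),
  c(-0.5, 1.0, -1.0, 0.0, 0.0),
  c(0.23333333333333334, -0.5833333333333334, 1.0, -1.0, 0.0, 2.0),
  c(-0.08333333333333333, 0.25, -0.5833333333333334, 1.0, -1.0, 0.0, 0.0),
  c(0.024603174603174603, -0.08611111111111111, 0.25, -0.5833333333333334, 1.0, -1.0, 0.0, 2.0),
  c(-0.00625, 0.025, -0.08611111111111111, 0.25, -0.5833333333333334, 1.0, -1.0, 0.0, 0.0),
  c(0.0013999118165784832, -0.006299603174603175, 0.025, -0.08611111111111111, 0.25, -0.5833333333333334, 1.0, -1.0, 0.0, 2.0),
  c(-0.0002810846560846561, 0.0014054232804232803, -0.006299603174603175, 0.025, -0.08611111111111111, 0.25, -0.5833333333333334, 1.0, -1.0, 0.0, 0.0),
  c(5.120650953984287e-05, -0.0002816358024691358, 0.0014054232804232803, -0.006299603174603175, 0.025, -0.08611111111111111, 0.25, -0.5833333333333334, 1.0, -1.0, 0.0, 2.0),
  c(-8.542768959435627e-06, 5.1256613756613754e-05, -0.0002816358024691358, 0.0014054232804232803, -0.006299603174603175, 0.025, -0.08611111111111111, 0.25, -0.5833333333333334, 1.0, -1.0, 0.0, 0.0),
  c(1.3149145093589538e-06, -8.5469443108332e-06, 5.1256613756613754e-05, -0.0002816358024691358, 0.0014054232804232803, -0.006299603174603175, 0.025, -0.08611111111111111, 0.25, -0.5833333333333334, 1.0, -1.0, 0.0, 2.0)
)
.msd_zeta_series_b <- list(
  c(-2.0, -2.0),
  c(1.0, 0.0, 0.0),
  c(-0.3333333333333333, 0.0, -2.0, -2.0),
  c(0.08333333333333333, 0.0, 1.0, 0.0, 0.0),
  c(-0.016666666666666666, 0.0, -0.3333333333333333, 0.0, -2.0, -2.0),
  c(0.002777777777777778, 0.0, 0.08333333333333333, 0.0, 1.0, 0.0, 0.0),
  c(-0.0003968253968253968, 0.0, -0.016666666666666666, 0.0, -0.3333333333333333, 0.0, -2.0, -2.0),
  c(4.96031746031746e-05, 0.0, 0.002777777777777778, 0.0, 0.08333333333333333, 0.0, 1.0, 0.0, 0.0),
  c(-5.5114638447971785e-06, 0.0, -0.0003968253968253968, 0.0, -0.016666666666666666, 0.0, -0.3333333333333333, 0.0, -2.0, -2.0),
  c(5.511463844797178e-07, 0.0, 4.96031746031746e-05, 0.0, 0.002777777777777778, 0.0, 0.08333333333333333, 0.0, 1.0, 0.0, 0.0),
  c(-5.010421677088344e-08, 0.0, -5.5114638447971785e-06, 0.0, -0.0003968253968253968, 0.0, -0.016666666666666666, 0.0, -0.3333333333333333, 0.0, -2.0, -2.0)
)
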