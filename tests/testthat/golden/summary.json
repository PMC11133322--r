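{
  "sign_accuracy_posterior": 0.916666666666667,
  "knockout_success_rate": 1,
  "knockout_mean_rank": 1,
  "qs_mean_improvement": -0.0182785119083438,
  "rbo_mean": 0.984510042898551
}
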