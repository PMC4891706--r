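{
  "name": "overcautious",
  "attempt_curve": [
    {
      "width": 2.5,
      "prob": 0.15
    },
    {
      "width": 6,
      "prob": 0.02
    }
  ],
  "success_given_approach": [
    {
      "width": 2.5,
      "prob": 0.13
    },
    {
      "width": 4,
      "prob": 0.02
    }
  ],
  "fall_given_attempt": 0,
  "perception": {
    "gain": 1,
    "c_clear": 0.2,
    "c_striped": 1.5
  },
  "speed_mean": 2,
  "speed_sd": 1,
  "turn_p0": 0.5,
  "persistence_tau": 60,
  "crossing_duration": 3,
  "approach_refractory": 60
}
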