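{
  "name": "super_climber",
  "attempt_curve": [
    {
      "width": 2.5,
      "prob": 0.9
    },
    {
      "width": 6,
      "prob": 0.35
    }
  ],
  "success_given_approach": [
    {
      "width": 2.5,
      "prob": 0.7
    },
    {
      "width": 4,
      "prob": 0.133333333333333
    }
  ],
  "fall_given_attempt": 0.01,
  "perception": {
    "gain": 1,
    "c_clear": 0.2,
    "c_striped": 1.5
  },
  "speed_mean": 11,
  "speed_sd": 3,
  "turn_p0": 0.5,
  "persistence_tau": 60,
  "crossing_duration": 3,
  "approach_refractory": 60
}
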