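{
  "k": 0.3,
  "l_max": 354,
  "unit": "mm",
  "n_cohorts": 11,
  "ages": [1, 2, 3, 4, 5, 6, 7, 8, 9],
  "noise_sd": 2,
  "l_first": 100,
  "first_year": 1985,
  "seed": 42,
  "rng": "Mersenne-Twister",
  "k_at_age": {
    "1": 0.15,
    "2": 0.15,
    "3": 0.3,
    "4": 0.3,
    "5": 0.3,
    "6": 0.3,
    "7": 0.3,
    "8": 0.3,
    "9": 0.3
  },
  "birth_years": [1984, 1985, 1986, 1987, 1988, 1989, 1990, 1991, 1992, 1993, 1994]
}
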