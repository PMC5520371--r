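{
  "continuous": ["bweight", "gestage", "apgar"],
  "categorical": ["sex", "smoking"],
  "profiles": [
    {
      "levels": {
        "sex": 0,
        "smoking": 0
      },
      "prob_singleton": 0.3456,
      "prob_twin": 0.3648
    },
    {
      "levels": {
        "sex": 1,
        "smoking": 0
      },
      "prob_singleton": 0.3744,
      "prob_twin": 0.3952
    },
    {
      "levels": {
        "sex": 0,
        "smoking": 1
      },
      "prob_singleton": 0.1344,
      "prob_twin": 0.1152
    },
    {
      "levels": {
        "sex": 1,
        "smoking": 1
      },
      "prob_singleton": 0.1456,
      "prob_twin": 0.1248
    }
  ],
  "mvn": {
    "sex=0,smoking=0": {
      "singleton": {
        "mean": {
          "bweight": 745,
          "gestage": 26.3,
          "apgar": 6.3
        },
        "cov": [
          [25600, 144, 80],
          [144, 2.25, 0.6],
          [80, 0.6, 4]
        ]
      },
      "twin_pair": {
        "mean": {
          "bweight.1": 680,
          "gestage.1": 25.9,
          "apgar.1": 6.1,
          "bweight.2": 680,
          "gestage.2": 25.9,
          "apgar.2": 6.1
        },
        "cov": [
          [22500, 111.792047381433, 68.7386354243376, 15750, 104.890743156868, 34.3693177121688],
          [111.792047381433, 1.96, 0.352040117178935, 104.890743156868, 1.9404, 0.305187155693027],
          [68.7386354243376, 0.352040117178935, 4, 34.3693177121688, 0.305187155693027, 1.2],
          [15750, 104.890743156868, 34.3693177121688, 22500, 111.792047381433, 68.7386354243376],
          [104.890743156868, 1.9404, 0.305187155693027, 111.792047381433, 1.96, 0.352040117178935],
          [34.3693177121688, 0.305187155693027, 1.2, 68.7386354243376, 0.352040117178935, 4]
        ]
      }
    },
    "sex=1,smoking=0": {
      "singleton": {
        "mean": {
          "bweight": 790,
          "gestage": 26.3,
          "apgar": 6
        },
        "cov": [
          [25600, 144, 80],
          [144, 2.25, 0.6],
          [80, 0.6, 4]
        ]
      },
      "twin_pair": {
        "mean": {
          "bweight.1": 725,
          "gestage.1": 25.9,
          "apgar.1": 5.8,
          "bweight.2": 725,
          "gestage.2": 25.9,
          "apgar.2": 5.8
        },
        "cov": [
          [22500, 111.792047381433, 68.7386354243376, 15750, 104.890743156868, 34.3693177121688],
          [111.792047381433, 1.96, 0.352040117178935, 104.890743156868, 1.9404, 0.305187155693027],
          [68.7386354243376, 0.352040117178935, 4, 34.3693177121688, 0.305187155693027, 1.2],
          [15750, 104.890743156868, 34.3693177121688, 22500, 111.792047381433, 68.7386354243376],
          [104.890743156868, 1.9404, 0.305187155693027, 111.792047381433, 1.96, 0.352040117178935],
          [34.3693177121688, 0.305187155693027, 1.2, 68.7386354243376, 0.352040117178935, 4]
        ]
      }
    },
    "sex=0,smoking=1": {
      "singleton": {
        "mean": {
          "bweight": 700,
          "gestage": 26,
          "apgar": 6.3
        },
        "cov": [
          [25600, 144, 80],
          [144, 2.25, 0.6],
          [80, 0.6, 4]
        ]
      },
      "twin_pair": {
        "mean": {
          "bweight.1": 635,
          "gestage.1": 25.6,
          "apgar.1": 6.1,
          "bweight.2": 635,
          "gestage.2": 25.6,
          "apgar.2": 6.1
        },
        "cov": [
          [22500, 111.792047381433, 68.7386354243376, 15750, 104.890743156868, 34.3693177121688],
          [111.792047381433, 1.96, 0.352040117178935, 104.890743156868, 1.9404, 0.305187155693027],
          [68.7386354243376, 0.352040117178935, 4, 34.3693177121688, 0.305187155693027, 1.2],
          [15750, 104.890743156868, 34.3693177121688, 22500, 111.792047381433, 68.7386354243376],
          [104.890743156868, 1.9404, 0.305187155693027, 111.792047381433, 1.96, 0.352040117178935],
          [34.3693177121688, 0.305187155693027, 1.2, 68.7386354243376, 0.352040117178935, 4]
        ]
      }
    },
    "sex=1,smoking=1": {
      "singleton": {
        "mean": {
          "bweight": 745,
          "gestage": 26,
          "apgar": 6
        },
        "cov": [
          [25600, 144, 80],
          [144, 2.25, 0.6],
          [80, 0.6, 4]
        ]
      },
      "twin_pair": {
        "mean": {
          "bweight.1": 680,
          "gestage.1": 25.6,
          "apgar.1": 5.8,
          "bweight.2": 680,
          "gestage.2": 25.6,
          "apgar.2": 5.8
        },
        "cov": [
          [22500, 111.792047381433, 68.7386354243376, 15750, 104.890743156868, 34.3693177121688],
          [111.792047381433, 1.96, 0.352040117178935, 104.890743156868, 1.9404, 0.305187155693027],
          [68.7386354243376, 0.352040117178935, 4, 34.3693177121688, 0.305187155693027, 1.2],
          [15750, 104.890743156868, 34.3693177121688, 22500, 111.792047381433, 68.7386354243376],
          [104.890743156868, 1.9404, 0.305187155693027, 111.792047381433, 1.96, 0.352040117178935],
          [34.3693177121688, 0.305187155693027, 1.2, 68.7386354243376, 0.352040117178935, 4]
        ]
      }
    }
  },
  "truncation": {
    "apgar": {
      "rule": "apgar"
    }
  }
}
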