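{
  "version": "paper2012-v1",
  "seed": 20120712,
  "n_total": 2046,
  "incompleteness_prob": 0.0,
  "area_proportions": {
    "urban": 0.4643,
    "urban_rural": 0.2111,
    "rural": 0.3246
  },
  "man_prob_by_area": {
    "urban": 0.538,
    "urban_rural": 0.509,
    "rural": 0.563
  },
  "age_band_probs_by_area": {
    "urban": [
      0.348,
      0.343,
      0.309
    ],
    "urban_rural": [
      0.361,
      0.403,
      0.236
    ],
    "rural": [
      0.333,
      0.422,
      0.245
    ]
  },
  "occupation_probs_by_sex": {
    "man": {
      "employee": 0.78,
      "self_employed": 0.09,
      "housewife_fulltime": 0.0,
      "housewife_parttime": 0.0,
      "student": 0.003,
      "unemployed": 0.057,
      "other": 0.07
    },
    "woman": {
      "employee": 0.27,
      "self_employed": 0.04,
      "housewife_fulltime": 0.29,
      "housewife_parttime": 0.26,
      "student": 0.002,
      "unemployed": 0.058,
      "other": 0.08
    }
  },
  "income_probs_by_area": {
    "urban": [
      0.129,
      0.215,
      0.258,
      0.228,
      0.17
    ],
    "urban_rural": [
      0.199,
      0.299,
      0.238,
      0.157,
      0.107
    ],
    "rural": [
      0.182,
      0.298,
      0.264,
      0.155,
      0.101
    ]
  },
  "marriage_prob_by_area": {
    "urban": 0.62,
    "urban_rural": 0.66,
    "rural": 0.68
  },
  "exercise_habit_prob_by_area": {
    "urban": 0.346,
    "urban_rural": 0.37,
    "rural": 0.333
  },
  "anthropometry": {
    "height_mean_cm": {
      "man": 171,
      "woman": 158
    },
    "height_sd_cm": {
      "man": 6,
      "woman": 5.5
    },
    "bmi_mean": {
      "man": 23.2,
      "woman": 21.4
    },
    "bmi_sd": {
      "man": 3.2,
      "woman": 3.4
    }
  },
  "schedule": {
    "sleep": {
      "mean_min_weekday": 445,
      "mean_min_weekend": 480,
      "sd_min": 45,
      "wake_slot_mean_weekday": 26,
      "wake_slot_mean_weekend": 29,
      "wake_slot_sd": 2
    },
    "work": {
      "workday_prob_weekday": {
        "employee": 0.95,
        "self_employed": 0.9,
        "housewife_fulltime": 0.0,
        "housewife_parttime": 0.75,
        "student": 0.1,
        "unemployed": 0.0,
        "other": 0.6
      },
      "workday_prob_weekend": {
        "employee": 0.15,
        "self_employed": 0.35,
        "housewife_fulltime": 0.0,
        "housewife_parttime": 0.15,
        "student": 0.0,
        "unemployed": 0.0,
        "other": 0.2
      },
      "fulltime_mean_min": 510,
      "parttime_mean_min": 270,
      "sd_min": 70,
      "weekend_factor": 0.7,
      "parttime_occupations": [
        "housewife_parttime",
        "student"
      ],
      "job_type_probs": {
        "man": {
          "urban": [
            0.82,
            0.13,
            0.05
          ],
          "urban_rural": [
            0.68,
            0.21,
            0.11
          ],
          "rural": [
            0.58,
            0.29,
            0.13
          ]
        },
        "woman": {
          "urban": [
            0.6,
            0.33,
            0.07
          ],
          "urban_rural": [
            0.56,
            0.36,
            0.08
          ],
          "rural": [
            0.5,
            0.4,
            0.1
          ]
        }
      },
      "composition": {
        "sedentary": {
          "sitting": 0.86,
          "standing": 0.08,
          "walking": 0.06,
          "vigorous": 0.0
        },
        "standing": {
          "sitting": 0.25,
          "standing": 0.62,
          "walking": 0.1,
          "vigorous": 0.03
        },
        "physical": {
          "sitting": 0.15,
          "standing": 0.35,
          "walking": 0.15,
          "vigorous": 0.35
        }
      }
    },
    "commute": {
      "mode_probs_by_area": {
        "urban": {
          "walk": 0.16,
          "transit": 0.52,
          "car": 0.17,
          "cycle": 0.15
        },
        "urban_rural": {
          "walk": 0.07,
          "transit": 0.1,
          "car": 0.68,
          "cycle": 0.15
        },
        "rural": {
          "walk": 0.08,
          "transit": 0.12,
          "car": 0.7,
          "cycle": 0.1
        }
      },
      "walk_oneway_min": {
        "urban": 40,
        "urban_rural": 30,
        "rural": 30
      },
      "transit_ride_oneway_min": {
        "urban": 70,
        "urban_rural": 35,
        "rural": 45
      },
      "transit_access_walk_min": 22,
      "car_oneway_min": {
        "urban": 40,
        "urban_rural": 45,
        "rural": 54
      },
      "cycle_oneway_min": 20,
      "oneway_sd_min": 12
    },
    "errand": {
      "weekday_prob_nonworker": 0.6,
      "weekend_outing_prob": {
        "urban": 0.68,
        "urban_rural": 0.7,
        "rural": 0.78
      },
      "mode_probs_by_area": {
        "urban": {
          "walk": 0.22,
          "transit": 0.4,
          "car": 0.3,
          "cycle": 0.08
        },
        "urban_rural": {
          "walk": 0.12,
          "transit": 0.08,
          "car": 0.7,
          "cycle": 0.1
        },
        "rural": {
          "walk": 0.08,
          "transit": 0.07,
          "car": 0.8,
          "cycle": 0.05
        }
      },
      "leg_min_mean": 40,
      "activity_min_mean": 75
    },
    "household": {
      "child_prob": 0.6,
      "cooking_slots": {
        "housewife": {
          "weekday": 5,
          "weekend": 5
        },
        "woman": {
          "weekday": 3.5,
          "weekend": 4
        },
        "man": {
          "weekday": 0.7,
          "weekend": 1.2
        }
      },
      "cleaning_slots": {
        "housewife": {
          "weekday": 4,
          "weekend": 3
        },
        "woman": {
          "weekday": 1.5,
          "weekend": 3
        },
        "man": {
          "weekday": 0.4,
          "weekend": 1.5
        }
      },
      "laundry_slots": {
        "housewife": {
          "weekday": 2,
          "weekend": 2
        },
        "woman": {
          "weekday": 1,
          "weekend": 2
        },
        "man": {
          "weekday": 0.2,
          "weekend": 0.5
        }
      },
      "childcare_slots": {
        "housewife": {
          "weekday": 4,
          "weekend": 4
        },
        "woman": {
          "weekday": 2,
          "weekend": 3
        },
        "man": {
          "weekday": 0.5,
          "weekend": 2
        }
      },
      "shopping_slots": {
        "housewife": {
          "weekday": 2.5,
          "weekend": 2.5
        },
        "woman": {
          "weekday": 1.5,
          "weekend": 2.5
        },
        "man": {
          "weekday": 0.4,
          "weekend": 1.5
        }
      }
    },
    "gardening": {
      "prob_by_area": {
        "urban": 0.15,
        "urban_rural": 0.25,
        "rural": 0.35
      },
      "mean_min": 60,
      "sd_min": 30
    },
    "sport": {
      "prob_weekday_habit": 0.3,
      "prob_weekend_habit": 0.55,
      "prob_weekday_none": 0.04,
      "prob_weekend_none": 0.1,
      "duration_mean_min": 90,
      "duration_sd_min": 35
    }
  }
}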