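[
  {
    "name": "gmed_anterior",
    "group": "GMed",
    "section": "anterior",
    "cranial": [20.9694395537746, 111.889390641587, 55],
    "caudal": [-7.60529396651071, -20.725121019119, 65]
  },
  {
    "name": "gmed_middle",
    "group": "GMed",
    "section": "middle",
    "cranial": [-17.6548497859531, -33.7312578050821, 55],
    "caudal": [-21.2860996995375, 16.8625838123173, 85]
  },
  {
    "name": "gmed_posterior",
    "group": "GMed",
    "section": "posterior",
    "cranial": [-88.6273724068132, 93.7031033823002, 55],
    "caudal": [-9.31539468313906, -16.0266579151895, 69]
  },
  {
    "name": "gmax_anterior",
    "group": "GMax",
    "section": "anterior",
    "cranial": [-80.1542070276569, 95.4250871368516, 45],
    "caudal": [0.945209616631004, -44.2174365387667, 65]
  },
  {
    "name": "gmax_middle",
    "group": "GMax",
    "section": "middle",
    "cranial": [-91.8506815182708, 94.5248723723456, 40],
    "caudal": [4.3654110498877, -53.6143627466258, 65]
  },
  {
    "name": "gmax_posterior",
    "group": "GMax",
    "section": "posterior",
    "cranial": [-110.074088016422, 84.7704866951947, 35],
    "caudal": [7.78561248314438, -63.0112889544849, 65]
  },
  {
    "name": "tfl",
    "group": "TFL",
    "section": "whole",
    "cranial": [-4.19560932506193, 136.030929012059, 60],
    "caudal": [-11.0254953997674, -11.3281948112599, 68]
  },
  {
    "name": "piriformis",
    "group": "P",
    "section": "whole",
    "cranial": [-65.5290749180248, 74.5524889779249, 20],
    "caudal": [-2.47499181662568, -34.8205103309077, 55]
  }
]
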