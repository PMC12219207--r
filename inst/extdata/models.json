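{
  "models": [
    {
      "id": 1,
      "response": "BP",
      "regressors": ["M2", "H", "HM", "F", "R", "SC", "GA", "N"],
      "intercept": 130.938,
      "coefficients": [7.083, -58.424, 1.092, -5.986, 15.083, 2.502, 8.844, 15.475],
      "stats": {"n": 21, "r": 0.932, "R2": 0.869, "SE": 74.919, "F": 9.964, "RMSE": 63.633, "p": 0.00}
    },
    {
      "id": 2,
      "response": "MR",
      "regressors": ["M1", "M2", "H", "HM", "F", "ABC", "R", "SC", "GA", "N"],
      "intercept": -5.883,
      "coefficients": [1.652, -1.391, 8.146, -0.036, 0.382, 2.829, -0.159, 0.037, 1.816, -3.368],
      "stats": {"n": 22, "r": 0.993, "R2": 0.985, "SE": 6.408, "F": 73.25, "RMSE": 4.531, "p": 0.000}
    },
    {
      "id": 3,
      "response": "P",
      "regressors": ["M1", "M2", "H", "HM", "F", "ABC", "R", "SC", "GA", "N"],
      "intercept": -2.012,
      "coefficients": [0.991, -0.857, 2.114, -0.015, 0.186, -2.21, -0.134, 0.494, 0.88, -0.336],
      "stats": {"n": 21, "r": 0.996, "R2": 0.991, "SE": 2.057, "F": 111.297, "RMSE": 1.419, "p": 0.000}
    },
    {
      "id": 4,
      "response": "MV",
      "regressors": ["M1", "M2", "H", "HM", "F", "ABC", "R", "SC", "GA", "N"],
      "intercept": 0.829,
      "coefficients": [20.337, -16.462, 23.664, -0.284, 3.643, -76.508, -4.307, 11.289, 7.629, 0.173],
      "stats": {"n": 22, "r": 0.988, "R2": 0.977, "SE": 24.554, "F": 46.274, "RMSE": 17.362, "p": 0.000}
    },
    {
      "id": 5,
      "response": "E",
      "regressors": ["M1", "M2", "H", "HM", "F", "ABC", "R", "SC", "GA", "N"],
      "intercept": 34.948,
      "coefficients": [-3.766, 2.66, -1.387, 0.03, -0.39, 32.311, 1.77, -3.034, -1.006, -5.294],
      "stats": {"n": 21, "r": 0.944, "R2": 0.892, "SE": 9.735, "F": 8.23, "RMSE": 6.718, "p": 0.001}
    },
    {
      "id": 6,
      "response": "C",
      "regressors": ["M1", "M2", "H", "HM", "F", "ABC", "R", "SC", "GA", "N"],
      "intercept": -115.791,
      "coefficients": [-1.752, 14.189, -55.935, -0.063, -1.712, 263.177, 3.817, -8.104, -34.905, -70.874],
      "stats": {"n": 21, "r": 0.993, "R2": 0.986, "SE": 59.764, "F": 68.631, "RMSE": 41.241, "p": 0.001}
    },
    {
      "id": 7,
      "response": "MW",
      "regressors": ["M1", "M2", "H", "HM", "F", "ABC", "R", "SC", "GA", "N"],
      "intercept": -17.309,
      "coefficients": [8.481, -2.412, 12.147, 0.056, 0.32, 60.661, 1.641, 1.952, 2.1, -32.396],
      "stats": {"n": 21, "r": 0.996, "R2": 0.993, "SE": 18.435, "F": 133.996, "RMSE": 12.721, "p": 0.000}
    }
  ]
}
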