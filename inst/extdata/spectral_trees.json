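{
  "schema": "phenolProfiler spectral tree v1",
  "description": "HPLC-PDA-ESI-MSn spectral trees of 23 chromatographic peaks from Dendranthema indicum var. aromaticum flower extract, negative ionization, nominal (unit-resolution) masses; rel_intensity is percent of the level base peak.",
  "trees": [
    {
      "peak_id": "1", "rt_min": 3.59, "uv_lambda_max": [260], "precursor_mz": 499,
      "fragments": [
        {"mz": 481, "rel_intensity": 30},
        {"mz": 353, "rel_intensity": 10},
        {"mz": 191, "rel_intensity": 100},
        {"mz": 173, "rel_intensity": 60}
      ]
    },
    {
      "peak_id": "2", "rt_min": 10.64, "uv_lambda_max": [230, 300], "precursor_mz": 685,
      "fragments": [
        {"mz": 539, "rel_intensity": 100, "children": [
          {"mz": 377, "rel_intensity": 100}
        ]},
        {"mz": 523, "rel_intensity": 60},
        {"mz": 665, "rel_intensity": 35}
      ]
    },
    {
      "peak_id": "3", "rt_min": 11.17, "uv_lambda_max": [250, 340], "precursor_mz": 447,
      "fragments": [
        {"mz": 285, "rel_intensity": 100}
      ]
    },
    {
      "peak_id": "4", "rt_min": 11.81, "uv_lambda_max": [250, 330], "precursor_mz": 533,
      "fragments": [
        {"mz": 353, "rel_intensity": 100, "children": [
          {"mz": 309, "rel_intensity": 1},
          {"mz": 191, "rel_intensity": 100},
          {"mz": 179, "rel_intensity": 16},
          {"mz": 173, "rel_intensity": 6},
          {"mz": 135, "rel_intensity": 4}
        ]},
        {"mz": 335, "rel_intensity": 5},
        {"mz": 191, "rel_intensity": 8},
        {"mz": 173, "rel_intensity": 2}
      ]
    },
    {
      "peak_id": "5", "rt_min": 11.92, "uv_lambda_max": [240, 330], "precursor_mz": 515,
      "fragments": [
        {"mz": 353, "rel_intensity": 100, "children": [
          {"mz": 191, "rel_intensity": 100},
          {"mz": 179, "rel_intensity": 40},
          {"mz": 173, "rel_intensity": 10},
          {"mz": 135, "rel_intensity": 7}
        ]},
        {"mz": 335, "rel_intensity": 5},
        {"mz": 191, "rel_intensity": 4}
      ]
    },
    {
      "peak_id": "6", "rt_min": 12.30, "uv_lambda_max": [250, 270, 320], "precursor_mz": 187,
      "fragments": [
        {"mz": 169, "rel_intensity": 6},
        {"mz": 125, "rel_intensity": 100}
      ]
    },
    {
      "peak_id": "7", "rt_min": 13.05, "uv_lambda_max": [250, 290], "precursor_mz": 173,
      "fragments": [
        {"mz": 146, "rel_intensity": 8},
        {"mz": 131, "rel_intensity": 100},
        {"mz": 127, "rel_intensity": 15}
      ]
    },
    {
      "peak_id": "8", "rt_min": 13.32, "uv_lambda_max": [250, 270, 320], "precursor_mz": 569,
      "fragments": [
        {"mz": 551, "rel_intensity": 2},
        {"mz": 525, "rel_intensity": 100, "children": [
          {"mz": 507, "rel_intensity": 16},
          {"mz": 482, "rel_intensity": 18},
          {"mz": 427, "rel_intensity": 10},
          {"mz": 379, "rel_intensity": 28},
          {"mz": 235, "rel_intensity": 15},
          {"mz": 193, "rel_intensity": 100}
        ]},
        {"mz": 459, "rel_intensity": 4},
        {"mz": 417, "rel_intensity": 20},
        {"mz": 391, "rel_intensity": 10}
      ]
    },
    {
      "peak_id": "9", "rt_min": 13.99, "uv_lambda_max": [250, 350], "precursor_mz": 285,
      "fragments": [
        {"mz": 241, "rel_intensity": 35},
        {"mz": 217, "rel_intensity": 20},
        {"mz": 199, "rel_intensity": 25},
        {"mz": 175, "rel_intensity": 25}
      ]
    },
    {
      "peak_id": "10", "rt_min": 14.68, "uv_lambda_max": [300], "precursor_mz": 453,
      "fragments": [
        {"mz": 435, "rel_intensity": 2},
        {"mz": 411, "rel_intensity": 6},
        {"mz": 393, "rel_intensity": 100, "children": [
          {"mz": 363, "rel_intensity": 20},
          {"mz": 249, "rel_intensity": 30},
          {"mz": 231, "rel_intensity": 100, "children": [
            {"mz": 187, "rel_intensity": 100}
          ]},
          {"mz": 205, "rel_intensity": 35}
        ]}
      ]
    },
    {
      "peak_id": "11", "rt_min": 16.41, "uv_lambda_max": [270, 330], "precursor_mz": 269,
      "fragments": [
        {"mz": 225, "rel_intensity": 40},
        {"mz": 201, "rel_intensity": 12},
        {"mz": 149, "rel_intensity": 10}
      ]
    },
    {
      "peak_id": "12", "rt_min": 17.05, "uv_lambda_max": [250, 330], "precursor_mz": 299,
      "fragments": [
        {"mz": 284, "rel_intensity": 100, "children": [
          {"mz": 256, "rel_intensity": 100},
          {"mz": 227, "rel_intensity": 10},
          {"mz": 212, "rel_intensity": 5}
        ]}
      ]
    },
    {
      "peak_id": "13", "rt_min": 17.49, "uv_lambda_max": [250, 270, 340], "precursor_mz": 329,
      "fragments": [
        {"mz": 314, "rel_intensity": 100, "children": [
          {"mz": 299, "rel_intensity": 100},
          {"mz": 285, "rel_intensity": 10}
        ]}
      ]
    },
    {
      "peak_id": "14", "rt_min": 19.74, "uv_lambda_max": [260], "precursor_mz": 659,
      "fragments": [
        {"mz": 615, "rel_intensity": 100, "children": [
          {"mz": 573, "rel_intensity": 100}
        ]},
        {"mz": 591, "rel_intensity": 1},
        {"mz": 573, "rel_intensity": 1},
        {"mz": 505, "rel_intensity": 1},
        {"mz": 265, "rel_intensity": 2}
      ]
    },
    {
      "peak_id": "15", "rt_min": 21.30, "uv_lambda_max": [240, 310], "precursor_mz": 293,
      "fragments": [
        {"mz": 275, "rel_intensity": 100},
        {"mz": 265, "rel_intensity": 25},
        {"mz": 231, "rel_intensity": 45},
        {"mz": 205, "rel_intensity": 40},
        {"mz": 249, "rel_intensity": 90},
        {"mz": 193, "rel_intensity": 28},
        {"mz": 163, "rel_intensity": 20}
      ]
    },
    {
      "peak_id": "16", "rt_min": 23.33, "uv_lambda_max": [250, 310], "precursor_mz": null,
      "fragments": []
    },
    {
      "peak_id": "17", "rt_min": 24.73, "uv_lambda_max": [270, 330], "precursor_mz": 283,
      "fragments": [
        {"mz": 269, "rel_intensity": 100}
      ]
    },
    {
      "peak_id": "18", "rt_min": 26.61, "uv_lambda_max": [270, 330, 350], "precursor_mz": null,
      "fragments": []
    },
    {
      "peak_id": "19", "rt_min": 26.96, "uv_lambda_max": [270, 310], "precursor_mz": 313,
      "fragments": [
        {"mz": 295, "rel_intensity": 100},
        {"mz": 277, "rel_intensity": 45},
        {"mz": 215, "rel_intensity": 10},
        {"mz": 183, "rel_intensity": 18}
      ]
    },
    {
      "peak_id": "20", "rt_min": 27.33, "uv_lambda_max": [270, 320, 350], "precursor_mz": 309,
      "fragments": [
        {"mz": 291, "rel_intensity": 50},
        {"mz": 265, "rel_intensity": 10},
        {"mz": 247, "rel_intensity": 100}
      ]
    },
    {
      "peak_id": "21", "rt_min": 27.54, "uv_lambda_max": [270, 320], "precursor_mz": 309,
      "fragments": [
        {"mz": 291, "rel_intensity": 100},
        {"mz": 265, "rel_intensity": 32},
        {"mz": 247, "rel_intensity": 30}
      ]
    },
    {
      "peak_id": "22", "rt_min": 28.58, "uv_lambda_max": [310], "precursor_mz": 295,
      "fragments": [
        {"mz": 277, "rel_intensity": 100},
        {"mz": 265, "rel_intensity": 30}
      ]
    },
    {
      "peak_id": "23", "rt_min": 28.91, "uv_lambda_max": [270, 320, 350], "precursor_mz": 297,
      "fragments": [
        {"mz": 279, "rel_intensity": 100},
        {"mz": 251, "rel_intensity": 65},
        {"mz": 223, "rel_intensity": 20}
      ]
    }
  ]
}
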