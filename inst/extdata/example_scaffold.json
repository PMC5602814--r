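{
  "scaffold_id": "SYN-EXAMPLE",
  "configurations": [
    {
      "positions": [
        {
          "sidechains": [
            {
              "id": "p0_s0",
              "weight": 6.97,
              "probability": 0.217745729619225
            },
            {
              "id": "p0_s1",
              "weight": 21.4,
              "probability": 0.416680760299001
            },
            {
              "id": "p0_s2",
              "weight": 21.93,
              "probability": 0.365573510081774
            }
          ]
        },
        {
          "sidechains": [
            {
              "id": "p1_s0",
              "weight": 33.43,
              "probability": 0.126938286796149
            },
            {
              "id": "p1_s1",
              "weight": 17.96,
              "probability": 0.221803004993015
            },
            {
              "id": "p1_s2",
              "weight": 24.13,
              "probability": 0.223012917642216
            },
            {
              "id": "p1_s3",
              "weight": 10.96,
              "probability": 0.42824579056862
            }
          ]
        },
        {
          "sidechains": [
            {
              "id": "p2_s0",
              "weight": 26.87,
              "probability": 0.300180420835002
            },
            {
              "id": "p2_s1",
              "weight": 35.88,
              "probability": 0.39821753594384
            },
            {
              "id": "p2_s2",
              "weight": 14.81,
              "probability": 0.301602043221158
            }
          ]
        }
      ]
    },
    {
      "positions": [
        {
          "sidechains": [
            {
              "id": "p0_s0",
              "weight": 28.02,
              "probability": 0.554491777754379
            },
            {
              "id": "p0_s1",
              "weight": 13.74,
              "probability": 0.445508222245622
            }
          ]
        },
        {
          "sidechains": [
            {
              "id": "p1_s0",
              "weight": 15.5,
              "probability": 0.439991286774008
            },
            {
              "id": "p1_s1",
              "weight": 25.47,
              "probability": 0.560008713225992
            }
          ]
        },
        {
          "sidechains": [
            {
              "id": "p2_s0",
              "weight": 16.67,
              "probability": 0.243917866130742
            },
            {
              "id": "p2_s1",
              "weight": 26.77,
              "probability": 0.316376649231518
            },
            {
              "id": "p2_s2",
              "weight": 24.1,
              "probability": 0.43970548463774
            }
          ]
        }
      ]
    }
  ]
}
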