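{
  "test_id": "SVTT",
  "model": "2PL",
  "categories": [0, 1],
  "items": [
    {
      "id": "Item 1",
      "a": 2.13,
      "b": -3.081
    },
    {
      "id": "Item 2",
      "a": 3.027,
      "b": -3.094
    },
    {
      "id": "Item 3",
      "a": 1.094,
      "b": -4.799
    },
    {
      "id": "Item 4",
      "a": 2.405,
      "b": -3.41
    },
    {
      "id": "Item 5",
      "a": 14.644,
      "b": -2.715
    },
    {
      "id": "Item 6",
      "a": 14.644,
      "b": -2.715
    },
    {
      "id": "Item 7",
      "a": 14.644,
      "b": -2.715
    },
    {
      "id": "Item 8",
      "a": 1.778,
      "b": -3.404
    },
    {
      "id": "Item 9",
      "a": 3.435,
      "b": -3.196
    },
    {
      "id": "Item 10",
      "a": 1.297,
      "b": -3.361
    },
    {
      "id": "Item 11",
      "a": 1.952,
      "b": -3.326
    },
    {
      "id": "Item 12",
      "a": 1.296,
      "b": -3.468
    },
    {
      "id": "Item 13",
      "a": 1.266,
      "b": -3.584
    },
    {
      "id": "Item 14",
      "a": 1.405,
      "b": -3.39
    },
    {
      "id": "Item 15",
      "a": 1.996,
      "b": -2.566
    },
    {
      "id": "Item 16",
      "a": 1.039,
      "b": -2.864
    },
    {
      "id": "Item 17",
      "a": 1.388,
      "b": -2.033
    },
    {
      "id": "Item 18",
      "a": 1.823,
      "b": -2.423
    },
    {
      "id": "Item 19",
      "a": 1.656,
      "b": -1.918
    },
    {
      "id": "Item 20",
      "a": 1.419,
      "b": -1.286
    },
    {
      "id": "Item 21",
      "a": 1.375,
      "b": -1.782
    },
    {
      "id": "Item 22",
      "a": 1.435,
      "b": -2.303
    },
    {
      "id": "Item 23",
      "a": 1.455,
      "b": -2.005
    },
    {
      "id": "Item 24",
      "a": 1.134,
      "b": -2.585
    },
    {
      "id": "Item 25",
      "a": 0.575,
      "b": 0.131
    },
    {
      "id": "Item 26",
      "a": 0.829,
      "b": -2.049
    },
    {
      "id": "Item 27",
      "a": 1.43,
      "b": -1.39
    },
    {
      "id": "Item 28",
      "a": 0.917,
      "b": -2.242
    },
    {
      "id": "Item 29",
      "a": 0.911,
      "b": -1.503
    },
    {
      "id": "Item 30",
      "a": 1.288,
      "b": -1.655
    },
    {
      "id": "Item 31",
      "a": 0.765,
      "b": -2.764
    },
    {
      "id": "Item 32",
      "a": 1.288,
      "b": -1.193
    },
    {
      "id": "Item 33",
      "a": 0.918,
      "b": -3.312
    },
    {
      "id": "Item 34",
      "a": 0.662,
      "b": -3.207
    },
    {
      "id": "Item 35",
      "a": 0.833,
      "b": -3.143
    },
    {
      "id": "Item 36",
      "a": 1.144,
      "b": -0.33
    }
  ]
}
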