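{
  "test_id": "ROCFcopy",
  "model": "GRM",
  "categories": [0, 0.5, 1, 2],
  "items": [
    {
      "id": "Item 1",
      "a": 1.824,
      "boundaries": [-2.506, -1.542, 2.292]
    },
    {
      "id": "Item 2",
      "a": 2.547,
      "boundaries": [-2.428, -1.186, 2.262]
    },
    {
      "id": "Item 3",
      "a": 3.958,
      "boundaries": [-1.994, -1.2, 1.431]
    },
    {
      "id": "Item 4",
      "a": 3.125,
      "boundaries": [-2.25, -1.389, 1.583]
    },
    {
      "id": "Item 5",
      "a": 2.241,
      "boundaries": [-2.666, -1.605, 2.155]
    },
    {
      "id": "Item 6",
      "a": 2.125,
      "boundaries": [-2.746, -1.121, 2.496]
    },
    {
      "id": "Item 7",
      "a": 2.146,
      "boundaries": [-1.789, -1.412, 1.869]
    },
    {
      "id": "Item 8",
      "a": 2.832,
      "boundaries": [-2.355, -0.972, 1.91]
    },
    {
      "id": "Item 9",
      "a": 2.726,
      "boundaries": [-2.355, -1.424, 1.791]
    },
    {
      "id": "Item 10",
      "a": 2.002,
      "boundaries": [-2.44, -1.595, 2.096]
    },
    {
      "id": "Item 11",
      "a": 1.913,
      "boundaries": [-2.868, -1.579, 2.032]
    },
    {
      "id": "Item 12",
      "a": 2.705,
      "boundaries": [-2.356, -1.415, 1.773]
    },
    {
      "id": "Item 13",
      "a": 1.837,
      "boundaries": [-2.882, -1.543, 2.855]
    },
    {
      "id": "Item 14",
      "a": 1.592,
      "boundaries": [-2.917, -1.434, 2.552]
    },
    {
      "id": "Item 15",
      "a": 1.516,
      "boundaries": [-2.744, -1.595, 2.723]
    },
    {
      "id": "Item 16",
      "a": 1.293,
      "boundaries": [-3.064, -2.059, 7.59]
    },
    {
      "id": "Item 17",
      "a": 2.6,
      "boundaries": [-2.455, -1.323, 1.937]
    },
    {
      "id": "Item 18",
      "a": 1.587,
      "boundaries": [-3.009, -1.387, 2.604]
    }
  ]
}
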