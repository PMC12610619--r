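{
  "test_id": "ROCFimm",
  "model": "GRM",
  "categories": [0, 0.5, 1, 2],
  "items": [
    {
      "id": "Item 1",
      "a": 0.934,
      "boundaries": [-1.89, 1.059, 6.951]
    },
    {
      "id": "Item 2",
      "a": 1.717,
      "boundaries": [-1.759, -0.395, 6.382]
    },
    {
      "id": "Item 3",
      "a": 1.853,
      "boundaries": [-0.416, 0.434, 4.11]
    },
    {
      "id": "Item 4",
      "a": 1.833,
      "boundaries": [-1.023, -0.443, 5.823]
    },
    {
      "id": "Item 5",
      "a": 1.661,
      "boundaries": [-0.953, -0.378, 5.592]
    },
    {
      "id": "Item 6",
      "a": 1.381,
      "boundaries": [-0.531, 1.128, 4.842]
    },
    {
      "id": "Item 7",
      "a": 1.621,
      "boundaries": [0.637, 0.951, 4.397]
    },
    {
      "id": "Item 8",
      "a": 1.833,
      "boundaries": [-0.451, 0.781, 4.033]
    },
    {
      "id": "Item 9",
      "a": 0.965,
      "boundaries": [-0.033, 1.051, 6.667]
    },
    {
      "id": "Item 10",
      "a": 0.887,
      "boundaries": [2.139, 2.804, 6.293]
    },
    {
      "id": "Item 11",
      "a": 1.413,
      "boundaries": [-1.4, 0.15, 4.976]
    },
    {
      "id": "Item 12",
      "a": 1.038,
      "boundaries": [0.385, 1.292, 6.168]
    },
    {
      "id": "Item 13",
      "a": 1.214,
      "boundaries": [-1.898, -0.633, 10.005]
    },
    {
      "id": "Item 14",
      "a": 0.777,
      "boundaries": [-1.514, 0.342, 8.378]
    },
    {
      "id": "Item 15",
      "a": 0.708,
      "boundaries": [0.124, 0.991, 8.911]
    },
    {
      "id": "Item 16",
      "a": 0.852,
      "boundaries": [-0.734, -0.249, 8.532]
    },
    {
      "id": "Item 17",
      "a": 1.145,
      "boundaries": [-1.456, 1.252, 5.609]
    },
    {
      "id": "Item 18",
      "a": 0.779,
      "boundaries": [-1.282, 1.785, 7.766]
    }
  ]
}
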