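{
  "version": "5.2.1",
  "flags": {},
  "shapes": [
    {
      "label": "seedling",
      "points": [[10.0, 20.0], [42.0, 52.0]],
      "shape_type": "rectangle"
    },
    {
      "label": "seedling",
      "points": [[0.0, 0.0], [10.0, 0.0], [0.0, 8.0]],
      "shape_type": "polygon"
    },
    {
      "label": "seedling",
      "points": [[100.0, 100.0], [118.0, 104.0], [110.0, 126.0], [98.0, 118.0]],
      "shape_type": "polygon"
    },
    {
      "label": "seedling",
      "points": [[200.5, 300.25], [230.5, 330.25]],
      "shape_type": "rectangle"
    },
    {
      "label": "seedling",
      "points": [[400.0, 12.0], [426.0, 40.0]],
      "shape_type": "rectangle"
    }
  ],
  "imagePath": "scene_0001.ppm",
  "imageHeight": 512,
  "imageWidth": 512
}
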