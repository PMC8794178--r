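# Example pipeline configuration for readPipelineConfig().
# Sections and keys mirror pipelineConfig() / syntheticConfig() arguments;
# anything omitted keeps its default.
synthesis:
  nDishes: 3
  fieldsPerDish: 1
  fieldShape: [1800, 1800]
  cellsPerField: 200
  sizeMeans: [2600, 5000]
  sizeSd: 500
  textureEffect: 1.5
  seed: 202
segmentation:
  polarity: dark
  minPx: 2000
  maxPx: 8000
labelling:
  radius: 30
  threshold: 0.8
classifier:
  kind: cnn
  channels: dic
  maxEpochs: 10
seed: 6
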