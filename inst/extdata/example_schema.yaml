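# Column mapping for readCellTable(): keys name the columns of your CSV.
# Note the quotes around "y": bare y is a YAML 1.1 boolean.
slide: slide_name
cell: cell_index
"x": centroid_x
"y": centroid_y
region: compartment
markers:
  - CD3
  - CD68
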