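# Bundled datasets

- `iris.data` — Fisher's iris data in the literal UCI distribution layout
  (4 numeric attributes, species string last, no header). This file
  deliberately reproduces the two historically erroneous records of the
  UCI file: row 35 is `4.9,3.1,1.5,0.1` and row 38 is `4.9,3.1,1.5,0.1`
  (the corrected values, as shipped with R's `datasets::iris`, are
  `...,0.2` and `4.9,3.6,1.4,0.1`). The benchmark results this package
  reproduces are only attainable from the literal file: with it the
  global minimum of the unsquared within-cluster-distance objective at
  k = 3 is 96.6555 and the best Lloyd solution scores 97.3259; with the
  corrected data they are 96.5403 and 97.2046.
- `wine.data` — UCI wine recognition data (class label 1–3 first, then 13
  numeric attributes, no header).
- `zoo.data` is **not** bundled (no redistribution copy was available when
  this package was assembled). Place the UCI file here to enable the Zoo
  benchmark; it is loaded with the leading animal-name column as row names
  and the final type column as labels.
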