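# Demo three-season landscape configuration (same values as
# demo_landscapes()). Optima differ between seasons; maxima sum to the
# 1000-calorie ceiling; widths in attribute units; perception noise SD
# in calories.
seasons:
  - season: 1
    optima: {length: 57, width: 30, thickness: 70}
    maxima: {length: 500, width: 300, thickness: 200}
    widths: {length: 12, width: 12, thickness: 12}
    noise_sd: 5
  - season: 2
    optima: {length: 25, width: 72, thickness: 40}
    maxima: {length: 500, width: 300, thickness: 200}
    widths: {length: 12, width: 12, thickness: 12}
    noise_sd: 5
  - season: 3
    optima: {length: 80, width: 45, thickness: 15}
    maxima: {length: 500, width: 300, thickness: 200}
    widths: {length: 12, width: 12, thickness: 12}
    noise_sd: 5
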