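# Self-management banding cut-offs per long-form scale.
# Intervals are inclusive and resolved best-first at the two published
# overlapping boundaries, so they partition 0..scale_max exactly.
- scale_max: 16
  bands:
    good:       {lower: 12, upper: 16}
    average:    {lower: 9,  upper: 11}
    borderline: {lower: 6,  upper: 8}
    poor:       {lower: 0,  upper: 5}
- scale_max: 32
  bands:
    good:       {lower: 20, upper: 32}
    average:    {lower: 17, upper: 19}
    borderline: {lower: 12, upper: 16}
    poor:       {lower: 0,  upper: 11}
- scale_max: 48
  bands:
    good:       {lower: 30, upper: 48}
    average:    {lower: 24, upper: 29}
    borderline: {lower: 18, upper: 23}
    poor:       {lower: 0,  upper: 17}
- scale_max: 96
  bands:
    good:       {lower: 56, upper: 96}
    average:    {lower: 49, upper: 55}
    borderline: {lower: 41, upper: 48}
    poor:       {lower: 0,  upper: 40}
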