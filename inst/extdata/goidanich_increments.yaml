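# Daily downy-mildew development increments (percent/day) by daily mean
# temperature (degC) and daily mean relative humidity (%) bins.
# Simplified table patterned on the shape of the classic Goidanich tables
# for Plasmopara viticola: development is fastest near 20-25 degC under
# near-saturated air and falls off toward the margins. Replace with a full
# transcription of the original tables for operational use; bins are
# left-closed, right-open (topmost bin closed).
temp_bins: [10, 15, 20, 25, 30]
rh_bins: [60, 75, 90, 100]
increments:
  - [1, 2, 3]    # 10-15 degC
  - [2, 4, 6]    # 15-20 degC
  - [3, 6, 8]    # 20-25 degC
  - [2, 4, 6]    # 25-30 degC
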