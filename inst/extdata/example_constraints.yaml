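# Per-channel mode constraints for fitBatch(): two entries per channel
# (marker-negative, marker-positive component), each either fixed
# intensity bounds or quantiles of the stratum distribution; null leaves
# a side open.
CD3:
  - fixed: [null, 0.3]
  - fixed: [0.45, null]
CD68:
  - fixed: [null, null]
  - quantile: [0.9, null]
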