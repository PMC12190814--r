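# Frozen reference configuration.
# Produced by scripts/calibrate_config.R; do not edit by hand.
# Budgets under this configuration:
#   total trainable parameters (full):      5230007   (5.23 M)
#   fusion decoder parameters:               167940
#   conv-stem variant (B+MSFFD+IAFT):       5187748   (5.19 M)
#   forward MACs at (4, 128, 128, 128):  9749321472   (9.75 G)
in_channels: 4
num_classes: 4
stage_channels: [8, 32, 96, 288]
blocks_per_stage: [1, 2, 1, 3]
num_heads: [2, 4, 8, 8]
mlp_ratio: 2
gate_hidden: 659
iterations: 1
aggregation: sequential
decoder:
  align_width: 6
  fuse_width: 6
  head_width: 20
  se_hidden: [4, 16, 63, 227]
  num_heads: 2
  plain_width: 16
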