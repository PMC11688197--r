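name: conv+SE
num_classes: 10
input_size: 224
dropout: 0.2
blocks:
- in_channels: 16
  expand_channels: 16
  out_channels: 16
  dw_kernel: 3
  stride: 2
  attention: SE
  nonlinearity: relu
  expansion_type: conv1x1
  projection_type: conv1x1
  branch_channels: 16
  ghost_s: 2
  maam_reduction: 12.0
- in_channels: 16
  expand_channels: 72
  out_channels: 24
  dw_kernel: 3
  stride: 2
  attention: none
  nonlinearity: relu
  expansion_type: conv1x1
  projection_type: conv1x1
  branch_channels: 16
  ghost_s: 2
  maam_reduction: 12.0
- in_channels: 24
  expand_channels: 88
  out_channels: 24
  dw_kernel: 3
  stride: 1
  attention: none
  nonlinearity: relu
  expansion_type: conv1x1
  projection_type: conv1x1
  branch_channels: 24
  ghost_s: 2
  maam_reduction: 12.0
- in_channels: 24
  expand_channels: 96
  out_channels: 40
  dw_kernel: 5
  stride: 2
  attention: SE
  nonlinearity: hswish
  expansion_type: conv1x1
  projection_type: conv1x1
  branch_channels: 24
  ghost_s: 2
  maam_reduction: 12.0
- in_channels: 40
  expand_channels: 240
  out_channels: 40
  dw_kernel: 5
  stride: 1
  attention: SE
  nonlinearity: hswish
  expansion_type: conv1x1
  projection_type: conv1x1
  branch_channels: 40
  ghost_s: 2
  maam_reduction: 12.0
- in_channels: 40
  expand_channels: 240
  out_channels: 40
  dw_kernel: 5
  stride: 1
  attention: SE
  nonlinearity: hswish
  expansion_type: conv1x1
  projection_type: conv1x1
  branch_channels: 40
  ghost_s: 2
  maam_reduction: 12.0
- in_channels: 40
  expand_channels: 120
  out_channels: 48
  dw_kernel: 5
  stride: 1
  attention: SE
  nonlinearity: hswish
  expansion_type: conv1x1
  projection_type: conv1x1
  branch_channels: 40
  ghost_s: 2
  maam_reduction: 12.0
- in_channels: 48
  expand_channels: 144
  out_channels: 48
  dw_kernel: 5
  stride: 1
  attention: SE
  nonlinearity: hswish
  expansion_type: conv1x1
  projection_type: conv1x1
  branch_channels: 48
  ghost_s: 2
  maam_reduction: 12.0
- in_channels: 48
  expand_channels: 288
  out_channels: 96
  dw_kernel: 5
  stride: 2
  attention: SE
  nonlinearity: hswish
  expansion_type: conv1x1
  projection_type: conv1x1
  branch_channels: 48
  ghost_s: 2
  maam_reduction: 12.0
- in_channels: 96
  expand_channels: 576
  out_channels: 96
  dw_kernel: 5
  stride: 1
  attention: SE
  nonlinearity: hswish
  expansion_type: conv1x1
  projection_type: conv1x1
  branch_channels: 96
  ghost_s: 2
  maam_reduction: 12.0
- in_channels: 96
  expand_channels: 576
  out_channels: 96
  dw_kernel: 5
  stride: 1
  attention: SE
  nonlinearity: hswish
  expansion_type: conv1x1
  projection_type: conv1x1
  branch_channels: 96
  ghost_s: 2
  maam_reduction: 12.0
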