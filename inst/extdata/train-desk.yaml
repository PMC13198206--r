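# Desk-scale training profile for 64-px simulator tiles.
# Fields mirror train_config(); weights/augment blocks mirror
# loss_weights() / augment_config().
batch_size: 24
labeled_per_class: 4
n_classes: 3
iterations_per_epoch: 50
max_epochs: 8
patience_epochs: 8
lr: 1.0e-3
lr_decay: 0.9
lambda_u_rampup_iters: 400
weights:
  lambda_U: 7.5
  lambda_C: 0.1
  m: 13
  T: 0.5
  alpha: 2
  K: 2
augment:
  rgb_brightness: [0.9, 1.1]
  rgb_contrast: [0.9, 1.1]
  rgb_saturation: [0.9, 1.1]
  crop: 32
  rotate: true
  flip_h: 0.5
  flip_v: 0.5
  channel_brightness: [0.9, 1.1]
view_mode: HE
use_mixup: true
use_contrastive: true
use_rgb_aug: true
use_adaptive_stains: true
use_projection_heads: false
contrastive_kind: triplet
contrastive_aggregate: sum
encoder: smallconv
feature_dim: 64
seed: 1
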