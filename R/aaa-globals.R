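# Canonical joint names of the tracked 12-joint skeleton.
JOINT_NAMES <- c(
  "head", "left_elbow", "right_elbow", "left_hand", "right_hand",
  "left_knee", "right_knee", "left_foot", "right_foot",
  "hip_center", "left_hip", "right_hip"
)

SENSOR_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")
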