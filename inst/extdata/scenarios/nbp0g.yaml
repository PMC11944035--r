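# Neutral body posture in microgravity: semi-crouched float with forward
# neck flexion; line-of-sight drops ~15 deg (head orientation only, no load
# effect)
name: nbp0g
gravity_factor: 0
joint_angles:
  neck_flexion: 24
  shoulder_flexion: 39
  shoulder_abduction: 35
  elbow_flexion: 77
  elbow_pronation: 60
  hip_flexion: 55
  hip_abduction: 16
  hip_external_rotation: 17
  knee_flexion: 55
  ankle_plantarflexion: 21
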