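# Neutral body posture on Earth (relaxed standing, 1 g)
name: nbp1g
gravity_factor: 1
joint_angles:
  sternoclavicular_protraction: 23
  sternoclavicular_elevation: 11.5
  shoulder_flexion: 8
  shoulder_abduction: 10
  elbow_flexion: 8
  elbow_pronation: -20
  hip_flexion: -6
  hip_abduction: 5
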