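# Thorax-like layered phantom for a 100 MeV beam (thicknesses in cm).
regions:
  - material: muscle
    thickness_cm: 5.1
  - material: bone
    thickness_cm: 2.7
  - material: lung
    thickness_cm: 8.6
  - material: tissue
    thickness_cm: 22.6
voxels: 100
boundary: left
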