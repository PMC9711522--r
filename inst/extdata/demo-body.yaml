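# Minimal demonstration body: an ellipsoidal trunk and a tapering
# frustum tail, with a croc-like bulk air fraction.  Units: metres,
# kg/m^3; +x anterior, +z up.
posture: axial swim
air: medium
segments:
  - name: trunk
    kind: ellipsoid
    a: 1.0
    b: 0.5
    c: 0.6
    density: 850
    role: axial head-trunk
  - name: tail
    kind: frustum
    r1: 0.4
    r2: 0.1
    h: 2.0
    density: 1000
    role: axial tail
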