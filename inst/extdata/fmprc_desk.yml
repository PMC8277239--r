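# Desk-scale fmPRC experiment: inhibitory square-pulse probe of the
# reference heterogeneous ING rhythm.
kind: fmprc
seed: 1
scale: desk
cv: 0.15
mean_current: 20.4
n: 500
amplitude: -1600.0
duration: 0.1
n_phases: 32
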