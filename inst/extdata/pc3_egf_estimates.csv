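condition,K,lambda,D,C0
control,1.13e-3,5.07e-2,1.32e2,6.84e-4
EGF-25,1.04e-3,5.59e-2,1.59e2,6.42e-4
EGF-50,1.12e-3,6.94e-2,1.53e2,7.79e-4
EGF-75,1.12e-3,5.74e-2,1.64e2,6.81e-4
EGF-100,1.16e-3,6.13e-2,2.06e2,7.12e-4
EGF-125,1.11e-3,5.48e-2,2.40e2,7.68e-4
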