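# Several acceptance checks assert published quantitative values that the
# synthetic reference table does not reproduce; keep the runner going past
# them so the whole suite always reports.
options(testthat.progress.max_fails = 1000)
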