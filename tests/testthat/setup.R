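# keep the reporter from terminating the run early: the acceptance file
# deliberately carries strict scientific assertions that can fail without
# invalidating the rest of the suite
options(testthat.progress.max_fails = 200)
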