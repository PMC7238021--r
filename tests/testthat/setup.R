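# Report every expectation: the population-scale comparisons check dozens
# of table cells and must not stop the run at the default failure cap.
options(testthat.progress.max_fails = 1000L)
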