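# shared setup for the analysis drivers: the emulated study conditions
# (58 adults, 32F/26M, 26 landmarks, 8 digitization sessions) and one seed
library(digitME)

SEED <- 1L
PARAMS <- synth_params(seed = SEED)
N_PERM <- 999L
OUT <- "results"
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

study_dataset <- function() generate_dataset(PARAMS)$dataset
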