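# iTRAQ 4-plex channel layout: three tumor time points ratioed against the
# wild-type reference channel (117).
TIMEPOINT_CHANNELS <- c(T6 = "116", T9 = "115", T12 = "114")
REFERENCE_CHANNEL <- "117"
TIMEPOINTS <- names(TIMEPOINT_CHANNELS)
REPLICATES <- c("A", "B")
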