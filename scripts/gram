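#!/usr/bin/env Rscript
# Thin wrapper over the installed package's command-line entry point.
gram::gram_cli(commandArgs(trailingOnly = TRUE))
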