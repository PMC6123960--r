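#!/usr/bin/env Rscript
## Regenerates the packaged synthetic demonstration dataset under
## inst/extdata/ from the frozen default seed.  Run from the repo root.
library(stripemorph)
demo <- synthetic_clownfish_demo()
paths <- write_demo_files(demo, "inst/extdata")
cat("wrote:\n"); print(paths)
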