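## fixed 6-significant-digit formatting so that repeated runs produce
## byte-identical text outputs
.fmt <- function(x) trimws(formatC(x, digits = 6, format = "g"))

.deg2rad <- function(deg) deg * pi / 180

## longest run of consecutive nonzero entries in a vector
.maxRun <- function(v) {
  if (!length(v) || all(v == 0)) return(0L)
  r <- rle(v != 0)
  max(r$lengths[r$values])
}
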