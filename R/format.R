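# Report number rendering. Inputs are always plain decimals; rendered
# output uses "," as thousands separator and "." as decimal point
# regardless of locale, e.g. 51482.8767 -> "51,482.88".

format_amount <- function(x, decimals = 2) {
  formatC(x, format = "f", digits = decimals, big.mark = ",")
}
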