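base_params <- amd_parameters()

# brute-force discounting oracle: explicit end-of-year sum
sum_discounted <- function(utility, rate, years) {
  if (years == 0) return(0)
  s <- 0
  for (t in seq_len(years)) s <- s + utility / (1 + rate)^t
  s
}
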