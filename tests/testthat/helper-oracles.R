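# all permutations of 1..n, for exhaustive permutation-null enumeration
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1)
  out
}
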