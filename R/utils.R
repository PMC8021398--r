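# split by label in order of first appearance; locale-independent, so
# outputs (and their file digests) do not depend on LC_COLLATE
split_in_order <- function(x, labels) {
  labels <- as.character(labels)
  split(x, factor(labels, levels = unique(labels)))
}

# locale-independent sort for user-facing label vectors
sort_c <- function(x) sort(x, method = "radix")
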