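# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so substreams never perturb each other.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic substream seed from a base seed and integer tags; stays
# within 32-bit range.
sub_seed <- function(seed, ...) {
  tags <- c(...)
  h <- as.double(seed) %% 2147483647
  for (t in tags) h <- (h * 69069 + as.double(t) * 7919 + 1) %% 2147483647
  as.integer(h)
}

# 8-connected component labelling. EBImage::bwlabel is 4-connected, so
# diagonally adjacent 4-components are merged with a union-find pass.
label_components <- function(mask) {
  mask <- (mask > 0) * 1
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs (down-right and down-left)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  sel <- a > 0 & b > 0 & a != b
  if (any(sel)) mapply(union_, a[sel], b[sel])
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  sel <- a > 0 & b > 0 & a != b
  if (any(sel)) mapply(union_, a[sel], b[sel])
  roots <- vapply(seq_len(nlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Sizes (pixel counts) of labelled components.
component_sizes <- function(lab) {
  if (max(lab) == 0) return(integer(0))
  tabulate(lab[lab > 0], nbins = max(lab))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_field <- function(field, msg) {
  stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
}
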