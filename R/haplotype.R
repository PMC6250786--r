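## Ancestry-segment haplotypes.
##
## A haplotype is one chromosome copy represented as an ordered list of
## ancestry segments in 0-based half-open coordinates: a numeric boundary
## vector `b` of length k+1 with b[1] = 0 and b[k+1] = chromosome length,
## and a character ancestry vector `a` of length k giving the founder
## population of each interval [b[i], b[i+1]).  The canonical form is
## contiguous, full-coverage, with no zero-width segments and no two
## adjacent segments of equal ancestry.  These objects sit in the hot loop
## of the simulator, so they are plain two-element lists.

#' Construct a haplotype from segment boundaries and ancestries
#'
#' Builds the canonical merged form of a haplotype covering `[0, length)`
#' of one chromosome.  Coordinates are 0-based, half-open base pairs.
#'
#' @param bounds numeric vector of k+1 non-decreasing segment boundaries;
#'   must start at 0.
#' @param ancestry character vector of k founder-population labels
#'   ("AF16"/"HK104"), one per interval.
#' @return a haplotype: `list(b = boundaries, a = ancestries)` in canonical
#'   form (zero-width segments dropped, equal-ancestry neighbours merged).
#' @examples
#' haplotype(c(0, 5e6, 5e6, 2e7), c("AF16", "HK104", "HK104"))
#' @export
haplotype <- function(bounds, ancestry) {
  if (length(bounds) != length(ancestry) + 1L) {
    stop_validation("bounds must have exactly one more element than ancestry")
  }
  if (bounds[1] != 0) stop_validation("haplotype must start at coordinate 0")
  if (any(diff(bounds) < 0)) stop_validation("bounds must be non-decreasing")
  bad <- setdiff(unique(ancestry), POPULATIONS)
  if (length(bad)) {
    stop_validation(sprintf("unknown ancestry label(s): %s",
                            paste(bad, collapse = ", ")))
  }
  h <- canonical_segments(bounds, ancestry)
  if (length(h$a) == 0L) stop_validation("haplotype has zero total length")
  h
}

## Drop zero-width segments and merge adjacent equal-ancestry runs.
canonical_segments <- function(b, a) {
  k <- length(a)
  keep <- diff(b) > 0
  if (!all(keep)) {
    a <- a[keep]
    b <- c(b[-(k + 1L)][keep], b[k + 1L])
    k <- length(a)
  }
  if (k > 1L) {
    same <- a[-1L] == a[-k]
    if (any(same)) {
      first <- c(TRUE, !same)
      a <- a[first]
      b <- c(b[-(k + 1L)][first], b[k + 1L])
    }
  }
  list(b = b, a = a)
}

hap_length <- function(h) h$b[length(h$b)]

#' Ancestry of a haplotype at a position
#'
#' @param h a haplotype (see [haplotype()]).
#' @param pos base-pair position in `[0, length)`.
#' @return founder-population label of the segment containing `pos`.
#' @export
ancestry_at <- function(h, pos) {
  L <- hap_length(h)
  if (pos < 0 || pos >= L) {
    stop_usage(sprintf("position %s outside chromosome range [0, %s)", pos, L))
  }
  h$a[findInterval(pos, h$b)]
}

## Segments of `h` restricted to [u, v), returned as (b, a) pieces with the
## final boundary included.  Assumes 0 <= u < v <= length.
hap_slice <- function(h, u, v) {
  i <- findInterval(u, h$b)
  j <- findInterval(v, h$b, left.open = TRUE)
  if (j == i) {
    list(b = c(u, v), a = h$a[i])
  } else {
    list(b = c(u, h$b[(i + 1L):j], v), a = h$a[i:j])
  }
}

## Recombinant of a bivalent: alternate between the two parental haplotypes
## at the sorted breakpoints `xs`, starting from h1 if `first1`.  Returns a
## canonical haplotype.  With no (interior) breakpoints the leading parent
## haplotype is transmitted intact.
recombine_pair <- function(h1, h2, xs, first1) {
  L <- hap_length(h1)
  xs <- xs[xs > 0 & xs < L]
  if (length(xs) == 0L) return(if (first1) h1 else h2)
  parents <- if (first1) list(h1, h2) else list(h2, h1)
  bounds <- c(0, xs, L)
  n <- length(bounds) - 1L
  bs <- vector("list", n)
  as <- vector("list", n)
  for (k in seq_len(n)) {
    s <- hap_slice(parents[[(k - 1L) %% 2L + 1L]], bounds[k], bounds[k + 1L])
    bs[[k]] <- s$b[-length(s$b)]
    as[[k]] <- s$a
  }
  canonical_segments(c(unlist(bs), L), unlist(as))
}
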