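#' Fauchere-Pliska hydrophobicity scale
#'
#' The per-residue hydrophobicity values (Fauchere & Pliska 1983) used by
#' helical-wheel amphipathicity tools; glycine is the scale's zero.
#'
#' @format named numeric vector over the 20 standard one-letter codes.
#' @export
fp_scale <- c(A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54,
              Q = -0.22, E = -0.64, G = 0.00, H = 0.13, I = 1.80,
              L = 1.70, K = -0.99, M = 1.23, F = 1.79, P = 0.72,
              S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22)

seq_hydrophobicities <- function(seq) {
  aa <- strsplit(toupper(seq), "")[[1]]
  if (!length(aa)) stop("empty sequence")
  bad <- setdiff(unique(aa), names(fp_scale))
  if (length(bad))
    stop("non-standard residue(s) in sequence: ", paste(bad, collapse = ", "))
  unname(fp_scale[aa])
}

#' Mean hydrophobicity of a peptide segment
#'
#' Arithmetic mean of the per-residue Fauchere-Pliska values, the
#' HeliQuest-style `<H>`. Report with two decimals for display; full
#' precision is returned.
#'
#' @param seq amino-acid string (standard residues only).
#' @return mean hydrophobicity (Fauchere-Pliska units).
#' @export
#' @examples
#' round(mean_hydrophobicity("FLAMLNHVLNVDGFYFST"), 2)
mean_hydrophobicity <- function(seq) {
  mean(seq_hydrophobicities(seq))
}

#' Hydrophobic moment of a helical segment
#'
#' Eisenberg helical-wheel moment: residues are placed at `delta`-degree
#' intervals (100 degrees per residue for an alpha helix) and the
#' length-normalized vector sum of their hydrophobicities is returned:
#' `mu_H = (1/N) * || sum_n H_n (cos(n delta), sin(n delta)) ||`, n = 0..N-1.
#' Unlike the mean, `mu_H` is generally not permutation-invariant: it
#' measures the segregation of hydrophobic residues onto one helix face.
#'
#' @param seq amino-acid string.
#' @param delta helical twist per residue, degrees.
#' @return non-negative moment (Fauchere-Pliska units).
#' @export
hydrophobic_moment <- function(seq, delta = 100) {
  h <- seq_hydrophobicities(seq)
  ang <- (seq_along(h) - 1) * delta * pi / 180
  sqrt(sum(h * cos(ang))^2 + sum(h * sin(ang))^2) / length(h)
}

#' Amphipathicity summary of a helix segment
#'
#' @param seq amino-acid string of the segment.
#' @param start,end optional 1-based residue numbers in the parent protein
#'   (bookkeeping only).
#' @param delta helical twist per residue, degrees.
#' @return object of class `helix_segment` with `mean_h` and `mu_h`.
#' @export
helix_segment <- function(seq, start = NA_integer_, end = NA_integer_,
                          delta = 100) {
  structure(list(sequence = seq, start = start, end = end,
                 twist_delta = delta,
                 mean_h = mean_hydrophobicity(seq),
                 mu_h = hydrophobic_moment(seq, delta)),
            class = "helix_segment")
}

#' @export
print.helix_segment <- function(x, ...) {
  rng <- if (is.na(x$start)) "" else sprintf(" (%d-%d)", x$start, x$end)
  cat(sprintf("<helix_segment>%s %s\n  mean hydrophobicity <H> = %.2f\n  hydrophobic moment muH  = %.2f\n",
              rng, x$sequence, x$mean_h, x$mu_h))
  invisible(x)
}

#' Tabulate helix segments as a data.frame (TSV-ready)
#'
#' @param segments list of `helix_segment` objects.
#' @return data.frame `segment`, `start`, `end`, `mean_h`, `mu_h`.
#' @export
helix_table <- function(segments) {
  do.call(rbind, lapply(segments, function(s)
    data.frame(segment = s$sequence, start = s$start, end = s$end,
               mean_h = round(s$mean_h, 2), mu_h = round(s$mu_h, 2),
               stringsAsFactors = FALSE)))
}
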