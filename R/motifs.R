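#' Reverse complement of a PWM
#' @param x a \code{pwm}.
#' @return the \code{pwm} matching the reverse-complement motif.
#' @export
pwm_revcomp <- function(x) {
  m <- x$matrix[rev(seq_len(nrow(x$matrix))), c("T", "G", "C", "A"),
                drop = FALSE]
  colnames(m) <- c("A", "C", "G", "T")
  structure(list(tf_name = x$tf_name, matrix = m, background = x$background),
            class = "pwm")
}

pwm_logodds <- function(x) {
  log2(sweep(x$matrix, 2, x$background, "/"))
}

# log-odds scores of every window of one strand; NA where the window
# contains a non-ACGT base or runs off the sequence end
scan_one_strand <- function(codes, lo) {
  w <- nrow(lo)
  np <- length(codes) - w + 1L
  if (np < 1L) return(numeric(0))
  s <- numeric(np)
  for (j in seq_len(w)) {
    row <- lo[j, ]
    s <- s + row[codes[j:(j + np - 1L)]]
  }
  s
}

#' Scan sequences with a PWM on both strands
#'
#' Log-odds scoring against the PWM background at every position on both
#' strands; a position is a hit when its score reaches
#' \code{score_fraction} of the maximum achievable score. Windows containing
#' N (or any non-ACGT base) are skipped; sequences shorter than the motif
#' yield no hits.
#'
#' @param sequences named character vector of DNA sequences.
#' @param x a \code{pwm}.
#' @param score_fraction fraction of the maximal log-odds score required
#'   (default 0.8).
#' @return data.frame: seq_name, pos (1-based window start on the plus
#'   strand), strand, score.
#' @export
scan_pwm <- function(sequences, x, score_fraction = 0.8) {
  stopifnot(inherits(x, "pwm"), length(sequences) > 0L)
  lo_f <- pwm_logodds(x)
  lo_r <- pwm_logodds(pwm_revcomp(x))
  threshold <- score_fraction * sum(apply(lo_f, 1, max))
  out <- list()
  for (nm in names(sequences)) {
    codes <- match(strsplit(sequences[[nm]], "")[[1]],
                   c("A", "C", "G", "T"))
    for (str in c("+", "-")) {
      s <- scan_one_strand(codes, if (str == "+") lo_f else lo_r)
      hit <- which(!is.na(s) & s >= threshold)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          seq_name = nm, pos = hit, strand = str, score = s[hit],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(seq_name = character(), pos = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Motif enrichment of target vs background enhancers
#'
#' Sequences are binarised (>= 1 PWM hit) and each TF tested by a one-sided
#' hypergeometric test: drawing the target set from the pooled
#' target + background universe, how surprising is the observed number of
#' hit-bearing target sequences. TFs with p below \code{p_max} are enriched
#' and contribute TF-enhancer pairs for every target sequence they hit.
#'
#' @param target_seqs,background_seqs named character vectors of sequences
#'   (target must be non-empty).
#' @param pwms named list of \code{pwm} objects.
#' @param p_max enrichment threshold on the raw p-value (default 1e-5).
#' @param score_fraction passed to [scan_pwm()].
#' @return list with \code{table} (tf, hits_target, hits_background, p,
#'   enriched) and \code{pairs} (tf, enhancer, motif_hits for enriched TFs).
#' @export
motif_enrichment <- function(target_seqs, background_seqs, pwms,
                             p_max = 1e-5, score_fraction = 0.8) {
  if (!length(target_seqs)) stop("target sequence set is empty")
  stopifnot(length(background_seqs) > 0L)
  nt <- length(target_seqs); nb <- length(background_seqs)
  tab <- list(); pairs <- list()
  for (tf in names(pwms)) {
    ht <- scan_pwm(target_seqs, pwms[[tf]], score_fraction)
    hb <- scan_pwm(background_seqs, pwms[[tf]], score_fraction)
    kt <- length(unique(ht$seq_name))
    kb <- length(unique(hb$seq_name))
    K <- kt + kb
    p <- phyper(kt - 1, K, nt + nb - K, nt, lower.tail = FALSE)
    enr <- p < p_max
    tab[[tf]] <- data.frame(tf = tf, hits_target = kt, hits_background = kb,
                            p = p, enriched = enr, stringsAsFactors = FALSE)
    if (enr && kt > 0L) {
      cnt <- table(ht$seq_name)
      pairs[[tf]] <- data.frame(tf = tf, enhancer = names(cnt),
                                motif_hits = as.integer(cnt),
                                enrichment_p = p, stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, c(tab, list(make.row.names = FALSE))),
       pairs = if (length(pairs))
         do.call(rbind, c(pairs, list(make.row.names = FALSE)))
       else data.frame(tf = character(), enhancer = character(),
                       motif_hits = integer(), enrichment_p = numeric(),
                       stringsAsFactors = FALSE))
}
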