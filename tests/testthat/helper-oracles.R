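# Independent brute-force oracles, deliberately written against the plain
# textbook definitions rather than reusing any package internals.

oracle_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# Gotoh affine-gap dynamic programming; a gap of length k costs
# open + k * ext. type "local" clamps at zero and returns the matrix max;
# type "global" charges end gaps and returns the corner.
oracle_align_score <- function(a, b, open = 11, ext = 1,
                               type = c("local", "global"), mat = NULL) {
  type <- match.arg(type)
  if (is.null(mat)) mat <- oracle_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  neg <- -1e9
  M <- X <- Y <- matrix(neg, n + 1, m + 1)
  M[1, 1] <- 0
  if (type == "global") {
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      diag_in <- max(M[i, j], X[i, j], Y[i, j])
      if (type == "local") diag_in <- max(diag_in, 0)
      M[i + 1, j + 1] <- diag_in + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                             X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                             Y[i + 1, j] - ext)
      if (type == "local") {
        best <- max(best, M[i + 1, j + 1])
      }
    }
  }
  if (type == "local") best else max(M[n + 1, m + 1], X[n + 1, m + 1],
                                     Y[n + 1, m + 1])
}

# Brute-force ORF enumeration: every ATG, scanned codon by codon to its
# first in-frame stop; then reduced to the 5'-most ATG per (strand, frame,
# stop).
oracle_find_orfs <- function(contig, code = 9, min_len = 702) {
  tab <- Biostrings::getGeneticCode(as.character(code))
  rc <- paleodens::revcomp(contig)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else rc
    L <- nchar(s)
    chars <- strsplit(s, "")[[1]]
    for (start in seq_len(L - 2)) {
      if (substr(s, start, start + 2) != "ATG") next
      pos <- start
      stop_at <- NA
      while (pos + 2 <= L) {
        aa <- tab[paste(chars[pos:(pos + 2)], collapse = "")]
        if (!is.na(aa) && aa == "*") { stop_at <- pos; break }
        pos <- pos + 3
      }
      if (is.na(stop_at)) next
      nt_len <- stop_at + 3 - start
      if (nt_len < min_len) next
      rows[[length(rows) + 1]] <- data.frame(
        strand = strand, local_start = start - 1L,
        local_end = stop_at + 2L,    # 0-based half-open end
        nt_len = nt_len, frame = (start - 1L) %% 3L
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), nt_len = integer()))
  }
  df <- do.call(rbind, rows)
  # 5'-most ATG per stop-bounded segment
  df <- df[order(df$local_start), ]
  key <- paste(df$strand, df$frame, df$local_end)
  df <- df[!duplicated(key), ]
  L <- nchar(contig)
  # local_start/local_end are already 0-based half-open on the scanned strand
  data.frame(
    start = ifelse(df$strand == "+", df$local_start, L - df$local_end),
    end = ifelse(df$strand == "+", df$local_end, L - df$local_start),
    strand = df$strand, nt_len = df$nt_len
  )
}

random_protein <- function(n, first_m = FALSE) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  p <- paste(sample(aa, n, replace = TRUE), collapse = "")
  if (first_m) p <- sub("^.", "M", p)
  p
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
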