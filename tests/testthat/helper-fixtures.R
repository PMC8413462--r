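# Shared fixtures and independent oracles.

randomRNA <- function(n) paste0(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

revcompRNA <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste0(comp[rev(strsplit(x, "", fixed = TRUE)[[1]])], collapse = "")
}

writeFastaText <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Independent brute-force duplex oracle: enumerates every (substrate offset,
# length) contiguous antiparallel pairing with the guide side ending at
# boxStart - 1, and applies the tie-break rules (longest; most WC; 5'-most
# substrate window). Returns NULL or list(t, L, nWC).
bruteDuplex <- function(snoSeq, boxStart, substrate, minLen = 8L,
                        allowWobble = TRUE) {
  wc <- c(AU = TRUE, UA = TRUE, GC = TRUE, CG = TRUE)
  wob <- c(GU = TRUE, UG = TRUE)
  ok <- function(g, s) isTRUE(wc[paste0(g, s)]) ||
    (allowWobble && isTRUE(wob[paste0(g, s)]))
  g <- strsplit(snoSeq, "", fixed = TRUE)[[1]]
  s <- strsplit(substrate, "", fixed = TRUE)[[1]]
  gEnd <- boxStart - 1L
  if (gEnd < 1L) return(NULL)
  best <- NULL
  for (t in seq_along(s)) {
    for (L in seq_len(min(gEnd, length(s) - t + 1L))) {
      ks <- 0:(L - 1L)
      if (!all(mapply(function(k) ok(g[gEnd - k], s[t + k]), ks))) next
      nWC <- sum(mapply(function(k) isTRUE(wc[paste0(g[gEnd - k], s[t + k])]), ks))
      cand <- list(t = t, L = L, nWC = nWC)
      if (is.null(best) || cand$L > best$L ||
          (cand$L == best$L && cand$nWC > best$nWC)) best <- cand
    }
  }
  if (is.null(best) || best$L < minLen) NULL else best
}

# A sequence realizing one internal box C'/D' placement with chosen windows
# and stem I nucleotides; returns list(seq, cStart, dStart).
placedMotif <- function(cwin, dwin = "CUGA", minus1 = c("G", "C"),
                        minus2 = c("C", "G"), pre = 6L, spacer = 4L,
                        post = 6L) {
  # layout: [pre] dwin n1n n2n [spacer] b2 b1 L1 cwin [post]
  seq <- paste0(randomRNA(pre), dwin, minus1[2], minus2[2], randomRNA(spacer),
                minus2[1], minus1[1], "A", cwin, randomRNA(post))
  dStart <- pre + 1L
  cStart <- dStart + 4L + 2L + spacer + 3L
  list(seq = seq, cStart = cStart, dStart = dStart)
}
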