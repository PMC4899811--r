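# shared fixtures and independent oracles for the test suite

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# random string with (usually) one planted tandem repeat
rand_with_repeat <- function(max_len = 100L) {
  n <- sample(30:max_len, 1L)
  s <- rand_dna(n)
  if (stats::runif(1) < 0.7) {
    m <- rand_dna(sample(1:6, 1L))
    run <- strrep(m, sample(3:8, 1L))
    if (nchar(run) < n) {
      pos <- sample.int(n - nchar(run), 1L)
      substr(s, pos, pos + nchar(run) - 1L) <- run
    }
  }
  s
}

# independent family oracle: connected components of the explicit
# rotate-by-one / reverse-complement graph over all 4^k strings, canonical
# name = lexicographic minimum of the component
oracle_families <- function(k) {
  alph <- c("A", "C", "G", "T")
  all_s <- sort(do.call(paste0, expand.grid(rep(list(alph), k),
                                            stringsAsFactors = FALSE)))
  rot1 <- function(s) paste0(substr(s, 2L, k), substr(s, 1L, 1L))
  rc1 <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                           collapse = "")
  comp <- new.env(parent = emptyenv())
  groups <- list()
  for (s in all_s) {
    if (!is.null(comp[[s]])) next
    # BFS over the component
    queue <- s
    seen <- character(0)
    while (length(queue) > 0L) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      if (cur %in% seen) next
      seen <- c(seen, cur)
      queue <- c(queue, rot1(cur), rc1(cur))
    }
    seen <- sort(seen)
    for (m in seen) comp[[m]] <- seen[1L]
    groups[[seen[1L]]] <- seen
  }
  groups[order(names(groups))]
}

# bait set is expensive (~1 min); build once per test run
default_baits <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- design_bait_set(seed = 1L)
    cache
  }
})

# small synthetic world for unit tests (full-size world lives in
# test-acceptance.R)
small_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 11L, reference_length = 3000L,
                        n_reference_mst_loci = 4L,
                        n_extra_referential_loci = 5L,
                        n_samples = 2L, depth = 20)
      cache <<- simulate_genome(cfg)
    }
    cache
  }
})

qual_str <- function(q, n) strrep(intToUtf8(q + 33L), n)
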