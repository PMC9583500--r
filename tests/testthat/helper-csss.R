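# Shared fixtures, all built in code at test time.

# small deterministic expression matrix
tiny_expression <- function(n = 12, p = 3, seed = 42, label = "all") {
  set.seed(seed)
  expression_matrix(matrix(exp(rnorm(n * p, 5, 0.5)), n, p),
                    marker_names = paste0("m", seq_len(p)),
                    sample_labels = label)
}

# scenario scaled down for routine tests
small_scenario <- function(seed = 1, n = 2000) {
  rt_scenario_spec(seed = seed, n_cells = c(control = n, RT_d6 = n))
}

# a two-process spec with well-separated planted structure
two_process_spec <- function(seed = 3, n = 1500, noise_sigma = 0.05) {
  baseline <- c(A = 100, B = 200, C = 150, D = 300, E = 80, F = 120)
  tg <- matrix(0, 6, 2, dimnames = list(names(baseline), c("P1", "P2")))
  tg[c("A", "B"), 1] <- c(0.8, -0.6)
  tg[c("C", "D"), 2] <- c(0.7, 0.7)
  procs <- orthogonal_processes(tg, baseline)
  # sign-balanced fractions: planted amplitudes have zero population mean,
  # so the reference term stays identified with the baseline
  sub <- data.frame(name = c("s1", "s2", "s3", "s4"),
                    barcode = c("+0", "-0", "0+", "0-"),
                    main = c(0.25, 0.25, 0.15, 0.15),
                    stringsAsFactors = FALSE)
  names(sub)[3] <- "main"
  synthetic_spec(baseline = baseline, processes = procs, subpopulations = sub,
                 n_cells = c(main = n), noise_sigma = noise_sigma, seed = seed)
}

# minimal FCS 3.0/3.1 writer for fixtures (list mode, uniform datatype)
write_test_fcs <- function(path, m, channels, datatype = "F",
                           endian = "little", version = "FCS3.0",
                           bits = if (datatype == "D") 64L else 32L,
                           deferred_offsets = FALSE) {
  n <- nrow(m); p <- ncol(m)
  stopifnot(length(channels) == p)
  d <- "/"
  kv <- c("$MODE", "L", "$PAR", p, "$TOT", n, "$DATATYPE", datatype,
          "$BYTEORD", if (endian == "little") "1,2,3,4" else "4,3,2,1")
  for (j in seq_len(p))
    kv <- c(kv, paste0("$P", j, "N"), channels[j], paste0("$P", j, "B"), bits)
  header_len <- 58L
  make_text <- function(extra = character()) {
    paste0(d, paste(c(kv, extra), collapse = d), d)
  }
  txt <- make_text()
  text_beg <- header_len
  text_end <- text_beg + nchar(txt) - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + n * p * (bits %/% 8L) - 1L
  if (deferred_offsets) {
    # offsets live in TEXT ($BEGINDATA/$ENDDATA); header data fields are 0.
    repeat {
      txt <- make_text(c("$BEGINDATA", data_beg, "$ENDDATA", data_end))
      new_end <- text_beg + nchar(txt) - 1L
      new_beg <- new_end + 1L
      if (new_beg == data_beg) { text_end <- new_end; break }
      data_beg <- new_beg
      data_end <- data_beg + n * p * (bits %/% 8L) - 1L
    }
  }
  fmt <- function(x) formatC(x, width = 8, flag = " ")
  hdr <- paste0(version, "    ", fmt(text_beg), fmt(text_end),
                if (deferred_offsets) paste0(fmt(0), fmt(0))
                else paste0(fmt(data_beg), fmt(data_end)),
                fmt(0), fmt(0))   # no ANALYSIS segment
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  vals <- as.vector(t(m))
  if (datatype == "I") {
    writeBin(as.integer(vals), con, size = bits %/% 8L, endian = endian)
  } else {
    writeBin(as.double(vals), con, size = if (datatype == "D") 8L else 4L,
             endian = endian)
  }
  invisible(path)
}
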