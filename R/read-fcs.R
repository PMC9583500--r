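# Minimal FCS 3.0/3.1 reader: list-mode data, uniform $DATATYPE F/D/I.
# Layout: 58-byte ASCII header with segment offsets, a delimiter-separated
# TEXT keyword segment, then the DATA segment (event-major).

read_fcs_matrix <- function(path, channel_map = NULL, sample_label) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 58L))
  version <- substr(hdr, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version '", version, "' (FCS 3.0/3.1 only)")
  off <- function(a, b) as.numeric(trimws(substr(hdr, a, b)))
  text_beg <- off(11, 18); text_end <- off(19, 26)
  data_beg <- off(27, 34); data_end <- off(35, 42)

  seek(con, text_beg)
  txt <- rawToChar(readBin(con, "raw", text_end - text_beg + 1L))
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1L]]
  parts <- parts[seq_len(length(parts) %/% 2L * 2L)]
  kw <- parts[seq(2, length(parts), by = 2)]
  names(kw) <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))

  need <- function(k) {
    if (is.na(kw[k]) || !nzchar(kw[k])) stop("FCS keyword ", k, " missing")
    kw[[k]]
  }
  if (toupper(need("$MODE")) != "L") stop("only list-mode ($MODE L) FCS supported")
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- gsub("[^0-9]", "", need("$BYTEORD"))
  endian <- if (byteord %in% c("1234", "12")) "little"
            else if (byteord %in% c("4321", "21")) "big"
            else stop("unsupported $BYTEORD: ", kw[["$BYTEORD"]])
  bits <- as.integer(kw[paste0("$P", seq_len(n_par), "B")])
  channels <- as.character(kw[paste0("$P", seq_len(n_par), "N")])
  if (anyNA(channels)) stop("missing $PnN channel names")

  if (data_beg == 0 || data_end == 0) {  # offsets deferred to TEXT segment
    data_beg <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }
  seek(con, data_beg)
  nval <- n_par * n_tot
  vals <- switch(dtype,
    F = readBin(con, "numeric", nval, size = 4L, endian = endian),
    D = readBin(con, "numeric", nval, size = 8L, endian = endian),
    I = {
      if (length(unique(bits)) != 1L)
        stop("mixed $PnB widths not supported for $DATATYPE I")
      readBin(con, "integer", nval, size = bits[1L] %/% 8L,
              signed = bits[1L] > 16L, endian = endian)
    },
    stop("unsupported $DATATYPE: ", dtype))
  if (length(vals) != nval)
    stop("FCS data segment truncated: expected ", nval, " values, got ",
         length(vals))
  m <- matrix(as.double(vals), nrow = n_tot, ncol = n_par, byrow = TRUE)

  markers <- channels
  if (!is.null(channel_map)) {
    hit <- match(channels, names(channel_map))
    markers[!is.na(hit)] <- unname(channel_map[hit[!is.na(hit)]])
  }
  list(values = m, marker_names = markers, cell_ids = NULL,
       sample_labels = sample_label)
}
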