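#' Read an FCS 3.0/3.1 list-mode file
#'
#' Parses the HEADER, delimited TEXT segment and list-mode DATA segment of a
#' Flow Cytometry Standard file and returns the events as an [event_table()].
#' Values are returned exactly as stored (linear acquisition units); no
#' compensation or transform is applied. Supported data types are 32-bit
#' float (`$DATATYPE F`), 64-bit double (`D`) and unsigned integer (`I`,
#' uniform 8/16/32-bit widths), in either byte order.
#'
#' Channel roles are resolved by matching `role_map` patterns
#' (case-insensitive regular expressions) against the file's short (`$PnN`)
#' and long (`$PnS`) channel names. Instrument detector names are not
#' standardized, so the default map covers common BD-style naming and can be
#' overridden per run. Files written by [write_fcs()] carry their role
#' assignment in custom `LUCFLOWROLE:` keywords, which take precedence when
#' `role_map` is `NULL`.
#'
#' @param path path to an FCS file.
#' @param role_map named character vector of regular expressions, one per
#'   role, or `NULL` (default) to use stored role keywords if present and
#'   otherwise [default_role_map()] leniently (unmatched roles are left
#'   unassigned). When a map is passed explicitly every pattern must match
#'   exactly one channel; zero or several matches raise an ambiguity error
#'   listing the candidates.
#' @return an [event_table()].
#' @seealso [write_fcs()]
#' @export
read_fcs <- function(path, role_map = NULL) {
  if (!file.exists(path)) lf_contract(sprintf("file does not exist: %s", path))
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 58) lf_abort("format", "file too short to hold an FCS header")

  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    lf_abort("format", sprintf("unsupported FCS version '%s' (supported: FCS3.0, FCS3.1)",
                               version))

  off <- vapply(0:5, function(i) {
    s <- trimws(rawToChar(raw[(11 + 8 * i):(18 + 8 * i)]))
    if (s == "") 0 else suppressWarnings(as.numeric(s))
  }, numeric(1))
  if (anyNA(off)) lf_abort("format", "malformed header offsets")
  text_begin <- off[1]; text_end <- off[2]
  if (text_begin < 58 || text_end <= text_begin || text_end >= length(raw))
    lf_abort("format", "invalid TEXT segment offsets")

  text <- rawToChar(raw[(text_begin + 1):(text_end + 1)])
  kw <- parse_fcs_text(text)
  get_kw <- function(key, required = TRUE) {
    v <- kw[[toupper(key)]]
    if (is.null(v) && required)
      lf_abort("format", sprintf("required keyword %s missing", key))
    v
  }

  mode <- get_kw("$MODE")
  if (toupper(mode) != "L")
    lf_abort("format", sprintf("only list mode is supported ($MODE=%s)", mode))
  datatype <- toupper(get_kw("$DATATYPE"))
  if (!datatype %in% c("F", "D", "I"))
    lf_abort("format", sprintf("unsupported $DATATYPE '%s'", datatype))
  byteord <- get_kw("$BYTEORD")
  endian <- switch(byteord, "1,2,3,4" = "little", "4,3,2,1" = "big",
                   lf_abort("format", sprintf("unsupported $BYTEORD '%s'", byteord)))

  par <- as.integer(get_kw("$PAR"))
  tot <- as.integer(get_kw("$TOT"))
  if (is.na(par) || par < 1) lf_abort("format", "invalid $PAR")
  if (is.na(tot) || tot < 0) lf_abort("format", "invalid $TOT")

  short_names <- vapply(seq_len(par), function(i) {
    v <- kw[[sprintf("$P%dN", i)]]
    if (is.null(v)) sprintf("P%d", i) else v
  }, character(1))
  long_names <- vapply(seq_len(par), function(i) {
    kw[[sprintf("$P%dS", i)]] %||% ""
  }, character(1))
  bits <- vapply(seq_len(par), function(i) {
    as.integer(kw[[sprintf("$P%dB", i)]] %||% NA_character_)
  }, integer(1))
  if (anyNA(bits)) lf_abort("format", "missing $PnB keyword(s)")

  if (datatype == "F" && any(bits != 32))
    lf_abort("format", "$DATATYPE F requires $PnB 32")
  if (datatype == "D" && any(bits != 64))
    lf_abort("format", "$DATATYPE D requires $PnB 64")
  if (datatype == "I") {
    if (length(unique(bits)) != 1 || !bits[1] %in% c(8L, 16L, 32L))
      lf_abort("format", "integer data requires a uniform $PnB of 8, 16 or 32")
  }

  data_begin <- as.numeric(kw[["$BEGINDATA"]] %||% "0")
  data_end <- as.numeric(kw[["$ENDDATA"]] %||% "0")
  if (is.na(data_begin) || is.na(data_end) || data_begin <= 0) {
    data_begin <- off[3]; data_end <- off[4]
  }

  n_values <- par * tot
  bytes_per_value <- bits[1] / 8
  expected <- n_values * bytes_per_value
  if (tot > 0) {
    if (data_begin <= 0 || data_begin + expected - 1 > length(raw))
      lf_abort("integrity", sprintf(
        "truncated DATA segment: need %d bytes at offset %d, file has %d",
        expected, data_begin, length(raw)))
    avail <- data_end - data_begin + 1
    if (data_end > 0 && avail < expected)
      lf_abort("integrity", sprintf(
        "DATA segment holds %d bytes but %d declared events x %d parameters require %d",
        avail, tot, par, expected))
    seg <- raw[(data_begin + 1):(data_begin + expected)]
    values <- switch(datatype,
      F = readBin(seg, "numeric", n = n_values, size = 4, endian = endian),
      D = readBin(seg, "numeric", n = n_values, size = 8, endian = endian),
      I = read_unsigned(seg, n_values, bytes_per_value, endian))
    events <- matrix(values, nrow = tot, ncol = par, byrow = TRUE)
  } else {
    events <- matrix(numeric(0), nrow = 0, ncol = par)
  }
  colnames(events) <- short_names

  roles <- resolve_roles(kw, role_map, short_names, long_names)
  tube_id <- kw[["$FIL"]] %||% basename(path)
  event_table(events, channel_names = short_names, channel_roles = roles,
              tube_id = tube_id)
}

# 8/16-bit unsigned integers read natively; 32-bit read signed and wrapped.
read_unsigned <- function(seg, n, size, endian) {
  if (size < 4) {
    as.numeric(readBin(seg, "integer", n = n, size = size, signed = FALSE,
                       endian = endian))
  } else {
    v <- as.numeric(readBin(seg, "integer", n = n, size = 4, endian = endian))
    ifelse(v < 0, v + 2^32, v)
  }
}

# TEXT segment: <delim> key <delim> value <delim> ... <delim>. A delimiter
# inside a key or value is escaped by doubling, which strsplit renders as an
# empty token between two pieces.
parse_fcs_text <- function(text) {
  delim <- substr(text, 1, 1)
  body <- substr(text, 2, nchar(text))
  if (substr(body, nchar(body), nchar(body)) == delim)
    body <- substr(body, 1, nchar(body) - 1)
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  tokens <- character()
  i <- 1
  while (i <= length(parts)) {
    piece <- parts[i]; i <- i + 1
    while (i <= length(parts) && parts[i] == "") {
      nxt <- if (i + 1 <= length(parts)) parts[i + 1] else ""
      piece <- paste0(piece, delim, nxt)
      i <- i + 2
    }
    tokens <- c(tokens, piece)
  }
  if (length(tokens) %% 2 != 0)
    lf_abort("format", "TEXT segment has an odd number of fields")
  keys <- tokens[seq(1, length(tokens), by = 2)]
  vals <- tokens[seq(2, length(tokens), by = 2)]
  std <- startsWith(keys, "$")
  keys[std] <- toupper(keys[std])
  stats::setNames(as.list(vals), keys)
}

#' Default channel-role name patterns
#'
#' Case-insensitive regular expressions matched against `$PnN`/`$PnS` channel
#' names to assign analysis roles. Covers BD-style scatter naming and common
#' dye/fluorophore labels for the viability (LIVE/DEAD Violet), CFSE, and
#' Luciferase (AF647 secondary) channels.
#'
#' @return named character vector of patterns.
#' @export
default_role_map <- function() {
  c(fsc_a = "^FSC[-_. ]?A$",
    fsc_h = "^FSC[-_. ]?H$",
    ssc_a = "^SSC[-_. ]?A$",
    viability = "LIVE|VIOLET|VIVID|BV421|AMCYAN",
    cfse = "CFSE|FITC",
    luciferase = "LUC|AF647|APC")
}

resolve_roles <- function(kw, role_map, short_names, long_names) {
  explicit <- !is.null(role_map)
  if (!explicit) {
    stored <- kw[startsWith(names(kw), "LUCFLOWROLE:")]
    if (length(stored)) {
      roles <- unlist(stored)
      names(roles) <- sub("^LUCFLOWROLE:", "", names(roles))
      return(roles[roles %in% short_names])
    }
    role_map <- default_role_map()
  }
  roles <- character()
  for (role in names(role_map)) {
    hit <- which(grepl(role_map[[role]], short_names, ignore.case = TRUE) |
                 grepl(role_map[[role]], long_names, ignore.case = TRUE))
    if (length(hit) == 1) {
      roles[role] <- short_names[hit]
    } else if (explicit) {
      lf_abort("ambiguity", sprintf(
        "role '%s' pattern '%s' matched %d channels (candidates: %s)",
        role, role_map[[role]], length(hit),
        if (length(hit)) paste(short_names[hit], collapse = ", ") else "none"))
    }
  }
  roles
}

#' Write an EventTable to an FCS 3.1 file
#'
#' Emits a list-mode FCS 3.1 file with little-endian 32-bit float data
#' (`$DATATYPE F`), readable by [read_fcs()] with channel names and values
#' preserved to 32-bit float precision. The tube id is stored in `$FIL` and
#' the role assignment in custom `LUCFLOWROLE:` keywords so that round trips
#' preserve the full analysis context.
#'
#' @param table an [event_table()] with at least one channel.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path) {
  stopifnot(inherits(table, "lucflow_event_table"))
  events <- table$events
  if (ncol(events) == 0) lf_contract("cannot write a table with zero channels")
  if (length(events) && !all(is.finite(events)))
    lf_contract("cannot write non-finite event values")

  par <- ncol(events); tot <- nrow(events)
  delim <- "|"
  esc <- function(x) {
    x <- as.character(x)
    if (!nzchar(x)) lf_contract("FCS keyword values must be non-empty")
    gsub(delim, paste0(delim, delim), x, fixed = TRUE)
  }

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = sprintf("%010d", 0),   # fixed width, patched below
    "$ENDDATA"   = sprintf("%010d", 0),
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(par), "$TOT" = as.character(tot),
    "$FIL" = esc(table$tube_id))
  for (i in seq_len(par)) {
    rng <- if (tot > 0) max(1, ceiling(max(events[, i]))) else 262144
    kw <- c(kw, stats::setNames(
      c("32", "0,0", as.character(rng), esc(table$channel_names[i])),
      sprintf(c("$P%dB", "$P%dE", "$P%dR", "$P%dN"), i)))
  }
  for (role in names(table$channel_roles))
    kw[paste0("LUCFLOWROLE:", role)] <- esc(table$channel_roles[[role]])

  build_text <- function(kw) {
    paste0(delim, paste0(names(kw), delim, unname(kw), delim, collapse = ""))
  }
  text <- build_text(kw)
  text_begin <- 58
  text_end <- text_begin + nchar(text, type = "bytes") - 1
  n_bytes <- 4 * par * tot
  if (tot > 0) {
    data_begin <- text_end + 1
    data_end <- data_begin + n_bytes - 1
    kw["$BEGINDATA"] <- sprintf("%010d", data_begin)
    kw["$ENDDATA"] <- sprintf("%010d", data_end)
    text <- build_text(kw)
  } else {
    data_begin <- 0; data_end <- 0
  }

  hdr_off <- function(x) if (x > 99999999) sprintf("%8d", 0) else sprintf("%8d", x)
  header <- paste0("FCS3.1    ", hdr_off(text_begin), hdr_off(text_end),
                   hdr_off(data_begin), hdr_off(data_end),
                   sprintf("%8d%8d", 0, 0))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (tot > 0)
    writeBin(as.vector(t(events)), con, size = 4, endian = "little")
  invisible(path)
}
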