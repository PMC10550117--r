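# hand-rolled FCS builder so the reader is tested against bytes laid out
# independently of write_fcs()
build_fcs_bytes <- function(values, declared_par = ncol(values),
                            declared_tot = nrow(values),
                            names = paste0("Chan", seq_len(declared_par)),
                            version = "FCS3.1", delim = "/",
                            datatype = "F", byteord = "1,2,3,4") {
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", sprintf("%08d", 0), "$ENDDATA", sprintf("%08d", 0),
          "$BYTEORD", byteord, "$DATATYPE", datatype, "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(declared_par),
          "$TOT", as.character(declared_tot))
  size <- if (datatype == "I") 2L else 4L
  for (i in seq_len(declared_par))
    kw <- c(kw, sprintf("$P%dB", i), as.character(size * 8),
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dR", i), "262144",
            sprintf("$P%dN", i), names[i])
  text_of <- function(kw) paste0(delim, paste0(kw, collapse = delim), delim)
  text <- text_of(kw)
  data_begin <- 58 + nchar(text)
  n_bytes <- length(values) * size
  data_end <- data_begin + n_bytes - 1
  kw[which(kw == "$BEGINDATA") + 1] <- sprintf("%08d", data_begin)
  kw[which(kw == "$ENDDATA") + 1] <- sprintf("%08d", data_end)
  text <- text_of(kw)
  header <- sprintf("%s    %8d%8d%8d%8d%8d%8d", version, 58,
                    58 + nchar(text) - 1, data_begin, data_end, 0, 0)
  endian <- if (byteord == "1,2,3,4") "little" else "big"
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  if (datatype == "I") {
    writeBin(as.integer(t(values)), con, size = 2, endian = endian)
  } else {
    writeBin(as.vector(t(values)), con, size = 4, endian = endian)
  }
  rawConnectionValue(con)
}

write_bytes <- function(bytes) {
  path <- withr::local_tempfile(fileext = ".fcs", .local_envir = parent.frame())
  writeBin(bytes, path)
  path
}

test_that("read_fcs parses a byte-by-byte FCS 3.1 fixture with known values", {
  vals <- matrix(c(1.5, 20, 3.25, 400, 5, 600.5), nrow = 3, byrow = TRUE)
  path <- write_bytes(build_fcs_bytes(vals, names = c("FSC-A", "SSC-A")))
  et <- read_fcs(path, role_map = c(fsc_a = "^FSC-A$", ssc_a = "^SSC-A$"))
  expect_equal(unname(et$events), vals, tolerance = 1e-7)
  expect_equal(et$channel_names, c("FSC-A", "SSC-A"))
  expect_equal(unname(et$channel_roles[["fsc_a"]]), "FSC-A")
})

test_that("read_fcs handles FCS 3.0, big-endian and 16-bit integer data", {
  vals <- matrix(c(7, 8, 9, 10), nrow = 2, byrow = TRUE)
  p30 <- write_bytes(build_fcs_bytes(vals, version = "FCS3.0"))
  expect_equal(unname(read_fcs(p30)$events), vals, tolerance = 1e-7)

  pbe <- write_bytes(build_fcs_bytes(vals, byteord = "4,3,2,1"))
  expect_equal(unname(read_fcs(pbe)$events), vals, tolerance = 1e-7)

  pint <- write_bytes(build_fcs_bytes(vals, datatype = "I"))
  expect_equal(unname(read_fcs(pint)$events), vals)
})

test_that("read_fcs rejects unsupported versions and truncated data", {
  vals <- matrix(as.numeric(1:6), nrow = 3, byrow = TRUE)
  bad <- build_fcs_bytes(vals, version = "FCS2.0")
  expect_error(read_fcs(write_bytes(bad)), class = "lucflow_format_error",
               regexp = "FCS2.0")

  # TEXT declares 3 parameters but DATA holds only the 2 per event
  lying <- build_fcs_bytes(vals, declared_par = 3,
                           names = c("A", "B", "C"))
  expect_error(read_fcs(write_bytes(lying)), class = "lucflow_integrity_error")

  whole <- build_fcs_bytes(vals)
  expect_error(read_fcs(write_bytes(whole[1:(length(whole) - 8)])),
               class = "lucflow_integrity_error")
})

test_that("explicit role patterns matching zero or several channels are ambiguity errors", {
  vals <- matrix(as.numeric(1:4), nrow = 2, byrow = TRUE)
  path <- write_bytes(build_fcs_bytes(vals, names = c("FSC-A", "FSC-H")))
  expect_error(read_fcs(path, role_map = c(ssc_a = "^SSC-A$")),
               class = "lucflow_ambiguity_error")
  expect_error(read_fcs(path, role_map = c(fsc_a = "FSC")),
               class = "lucflow_ambiguity_error", regexp = "FSC-A, FSC-H")
})

test_that("write_fcs/read_fcs round-trip preserves names, roles and values", {
  withr::local_seed(42)
  for (n in c(0L, 1L, 17L, 1000L, 10000L)) {
    m <- matrix(stats::runif(n * 3, 0, 2^18), nrow = n, ncol = 3,
                dimnames = list(NULL, c("FSC-A", "SSC-A", "Luciferase-AF647-A")))
    et <- event_table(m, channel_roles = c(fsc_a = "FSC-A", ssc_a = "SSC-A",
                                           luciferase = "Luciferase-AF647-A"),
                      tube_id = sprintf("rt_%d", n))
    path <- withr::local_tempfile(fileext = ".fcs")
    write_fcs(et, path)
    back <- read_fcs(path)
    expect_identical(back$channel_names, et$channel_names)
    expect_identical(back$channel_roles, et$channel_roles)
    expect_identical(back$tube_id, et$tube_id)
    expect_equal(nrow(back$events), n)
    if (n > 0)  # 32-bit float storage: ~7 significant digits survive
      expect_lt(max(abs(back$events - et$events) / pmax(abs(et$events), 1)), 1e-6)
  }
})

test_that("channel names containing the TEXT delimiter survive a round trip", {
  m <- matrix(c(10, 20), nrow = 1,
              dimnames = list(NULL, c("LIVE|DEAD Violet-A", "CFSE-A")))
  et <- event_table(m, channel_roles = c(viability = "LIVE|DEAD Violet-A",
                                         cfse = "CFSE-A"))
  path <- withr::local_tempfile(fileext = ".fcs")
  write_fcs(et, path)
  expect_identical(read_fcs(path)$channel_names, colnames(m))
})

test_that("write_fcs enforces its contract", {
  et <- tiny_event_table(matrix(c(1, 2), 1, dimnames = list(NULL, c("A", "B"))),
                         roles = character())
  et$events[1, 1] <- NaN
  expect_error(write_fcs(et, tempfile()), class = "lucflow_contract_error")

  empty_chan <- structure(list(events = matrix(numeric(0), 2, 0),
                               channel_names = character(),
                               channel_roles = character(), tube_id = "x"),
                          class = "lucflow_event_table")
  expect_error(write_fcs(empty_chan, tempfile()), class = "lucflow_contract_error")
})

test_that("event_table validates its invariants", {
  m <- matrix(1:4, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(event_table(m, channel_roles = c(fsc_a = "C")),
               class = "lucflow_contract_error")
  expect_error(event_table(m, channel_roles = c(nonsense = "A")),
               class = "lucflow_contract_error")
  expect_error(event_table(matrix(c(1, Inf), 1, 2,
                                  dimnames = list(NULL, c("A", "B")))),
               class = "lucflow_contract_error")
  et <- event_table(m)
  expect_error(channel_values(et, "luciferase"), class = "lucflow_contract_error")
})
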