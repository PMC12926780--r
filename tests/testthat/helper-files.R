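# minimal ZIP writer (single entry, stored/uncompressed) so the archive
# import path can be exercised without a system zip binary or a checked-in
# binary fixture

# bitwise xor of two non-negative doubles < 2^32
xor32 <- function(a, b) {
  r <- 0; bit <- 1
  for (i in 1:32) {
    r <- r + bit * ((floor(a / bit) + floor(b / bit)) %% 2)
    bit <- bit * 2
  }
  r
}

crc32_table <- local({
  tab <- numeric(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (c %% 2 == 1) {
        # 0xEDB88320 xor (c >> 1), in double arithmetic
        xor32(floor(c / 2), 3988292384)
      } else floor(c / 2)
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- 4294967295
  for (b in as.integer(bytes)) {
    idx <- xor32(crc, b) %% 256
    crc <- xor32(floor(crc / 256), crc32_table[idx + 1])
  }
  xor32(crc, 4294967295)
}

pack_le <- function(x, nbytes) {
  out <- raw(nbytes)
  for (i in seq_len(nbytes)) {
    out[i] <- as.raw(x %% 256)
    x <- floor(x / 256)
  }
  out
}

write_stored_zip <- function(path, entry_name, lines) {
  data <- charToRaw(paste0(paste(lines, collapse = "\n"), "\n"))
  name <- charToRaw(entry_name)
  crc <- crc32(data)
  sz <- length(data)
  local_hdr <- c(charToRaw("PK\x03\x04"), pack_le(20, 2), pack_le(0, 2),
                 pack_le(0, 2), pack_le(0, 2), pack_le(0, 2),
                 pack_le(crc, 4), pack_le(sz, 4), pack_le(sz, 4),
                 pack_le(length(name), 2), pack_le(0, 2), name)
  central <- c(charToRaw("PK\x01\x02"), pack_le(20, 2), pack_le(20, 2),
               pack_le(0, 2), pack_le(0, 2), pack_le(0, 2), pack_le(0, 2),
               pack_le(crc, 4), pack_le(sz, 4), pack_le(sz, 4),
               pack_le(length(name), 2), pack_le(0, 2), pack_le(0, 2),
               pack_le(0, 2), pack_le(0, 2), pack_le(0, 4), pack_le(0, 4),
               name)
  eocd <- c(charToRaw("PK\x05\x06"), pack_le(0, 2), pack_le(0, 2),
            pack_le(1, 2), pack_le(1, 2), pack_le(length(central), 4),
            pack_le(length(local_hdr) + sz, 4), pack_le(0, 2))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(local_hdr, data, central, eocd), con)
  invisible(path)
}
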