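# Little-endian binary primitives shared by the BLOW5 container, the record
# payload codec and the index. Integers wider than 32 bits are carried as R
# doubles (exact for magnitudes below 2^53, which covers every field here;
# the reserved 64-bit sentinels are produced as explicit byte patterns).

slow5_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "slow5_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

wb_u8 <- function(x) as.raw(x)

wb_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")

wb_u32 <- function(x) {
  x <- as.numeric(x)
  x <- ifelse(x >= 2^31, x - 2^32, x)
  writeBin(as.integer(x), raw(), size = 4L, endian = "little")
}

wb_u64 <- function(x) {
  x <- as.numeric(x)
  b <- raw(8L)
  for (i in 1:8) {
    b[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  b
}

wb_i64 <- function(x) wb_u64(if (x < 0) x + 2^64 else x)

wb_f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8L, endian = "little")

wb_f32 <- function(x) writeBin(as.numeric(x), raw(), size = 4L, endian = "little")

wb_i16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")

# A cursor over a raw vector for exact-consumption parsing.
raw_cursor <- function(bytes) {
  cur <- new.env(parent = emptyenv())
  cur$bytes <- bytes
  cur$pos <- 1L
  cur
}

cur_take <- function(cur, n) {
  n <- as.integer(n)
  if (cur$pos + n - 1L > length(cur$bytes)) {
    slow5_error("slow5_corrupt", "corrupt record: truncated payload (needed %d bytes at offset %d)",
                n, cur$pos - 1L)
  }
  out <- cur$bytes[seq.int(cur$pos, length.out = n)]
  cur$pos <- cur$pos + n
  out
}

cur_remaining <- function(cur) length(cur$bytes) - cur$pos + 1L

rd_u8 <- function(cur) as.integer(cur_take(cur, 1L))

rd_i8 <- function(cur) {
  v <- as.integer(cur_take(cur, 1L))
  if (v >= 128L) v - 256L else v
}

rd_u16 <- function(cur) readBin(cur_take(cur, 2L), "integer", size = 2L,
                                signed = FALSE, endian = "little")

rd_i16 <- function(cur) readBin(cur_take(cur, 2L), "integer", size = 2L,
                                signed = TRUE, endian = "little")

rd_u32 <- function(cur) {
  v <- readBin(cur_take(cur, 4L), "integer", size = 4L, endian = "little")
  v <- as.numeric(v)
  if (v < 0) v + 2^32 else v
}

rd_i32 <- function(cur) readBin(cur_take(cur, 4L), "integer", size = 4L, endian = "little")

rd_u64 <- function(cur) {
  b <- as.numeric(as.integer(cur_take(cur, 8L)))
  sum(b * 256^(0:7))
}

rd_i64 <- function(cur) {
  u <- rd_u64(cur)
  if (u >= 2^63) u - 2^64 else u
}

rd_f64 <- function(cur) readBin(cur_take(cur, 8L), "double", size = 8L, endian = "little")

rd_f32 <- function(cur) readBin(cur_take(cur, 4L), "double", size = 4L, endian = "little")

rd_i16vec <- function(cur, n) {
  if (n == 0) return(integer())
  readBin(cur_take(cur, 2L * n), "integer", n = n, size = 2L,
          signed = TRUE, endian = "little")
}

# Shortest decimal representation that parses back to exactly the same
# double; used wherever floating point crosses into ASCII.
fmt_double <- function(x) {
  out <- character(length(x))
  special <- !is.finite(x)
  out[special] <- as.character(x[special])
  todo <- which(!special)
  for (digits in 1:17) {
    if (!length(todo)) break
    s <- sprintf(paste0("%.", digits, "g"), x[todo])
    ok <- as.numeric(s) == x[todo]
    out[todo[ok]] <- s[ok]
    todo <- todo[!ok]
  }
  out
}
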