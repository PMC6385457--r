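# 5x7 bitmap font for card labels. Drawing text straight into the pixel
# array keeps rendered cards byte-identical across machines (no device or
# system-font dependence). Glyphs cover digits, upper-case letters and the
# punctuation that category labels can contain; other characters render as
# a blank cell. Lower-case input is mapped to upper case.

.font5x7 <- c(
  "0" = "01110100011001110101110011000101110",
  "1" = "00100011000010000100001000010001110",
  "2" = "01110100010000100010001000100011111",
  "3" = "11111000100010000010000011000101110",
  "4" = "00010001100101010010111110001000010",
  "5" = "11111100001111000001000011000101110",
  "6" = "00110010001000011110100011000101110",
  "7" = "11111000010001000100010000100001000",
  "8" = "01110100011000101110100011000101110",
  "9" = "01110100011000101111000010001001100",
  "A" = "01110100011000111111100011000110001",
  "B" = "11110100011000111110100011000111110",
  "C" = "01110100011000010000100001000101110",
  "D" = "11100100101000110001100011001011100",
  "E" = "11111100001000011110100001000011111",
  "F" = "11111100001000011110100001000010000",
  "G" = "01110100011000010111100011000101111",
  "H" = "10001100011000111111100011000110001",
  "I" = "01110001000010000100001000010001110",
  "J" = "00111000100001000010000101001001100",
  "K" = "10001100101010011000101001001010001",
  "L" = "10000100001000010000100001000011111",
  "M" = "10001110111010110101100011000110001",
  "N" = "10001100011100110101100111000110001",
  "O" = "01110100011000110001100011000101110",
  "P" = "11110100011000111110100001000010000",
  "Q" = "01110100011000110001101011001001101",
  "R" = "11110100011000111110101001001010001",
  "S" = "01111100001000001110000010000111110",
  "T" = "11111001000010000100001000010000100",
  "U" = "10001100011000110001100011000101110",
  "V" = "10001100011000110001100010101000100",
  "W" = "10001100011000110101101011010101010",
  "X" = "10001100010101000100010101000110001",
  "Y" = "10001100010101000100001000010000100",
  "Z" = "11111000010001000100010001000011111",
  "-" = "00000000000000001110000000000000000",
  "." = "00000000000000000000000000110000110",
  "/" = "00001000100001000100010001000010000",
  " " = "00000000000000000000000000000000000"
)

glyph_matrix <- function(ch) {
  bits <- .font5x7[[toupper(ch)]]
  if (is.null(bits)) bits <- .font5x7[[" "]]
  bits <- gsub(" ", "0", bits)
  matrix(strsplit(bits, "")[[1]] == "1", nrow = 5L, ncol = 7L)
}

# Width in pixels of `text` at integer `scale` (1 px tracking per glyph).
text_width_px <- function(text, scale) {
  n <- nchar(text)
  if (n == 0L) return(0L)
  as.integer(n * 6L * scale - scale)
}

text_height_px <- function(scale) as.integer(7L * scale)

# Plane indices covering `text` with its top-left at (x, y).
idx_text <- function(dm, text, x, y, scale = 2L) {
  chars <- strsplit(toupper(text), "")[[1]]
  gx <- integer(0); gy <- integer(0)
  cx <- round(x); cy <- round(y)
  block <- 0:(scale - 1L)
  bx <- rep(block, times = scale)
  by <- rep(block, each = scale)
  for (ch in chars) {
    g <- glyph_matrix(ch)
    on <- which(g, arr.ind = TRUE)
    if (nrow(on)) {
      px <- rep(cx + (on[, 1L] - 1L) * scale, each = length(bx)) + bx
      py <- rep(cy + (on[, 2L] - 1L) * scale, each = length(by)) + by
      gx <- c(gx, px); gy <- c(gy, py)
    }
    cx <- cx + 6L * scale
  }
  idx_from_xy(dm, gx, gy)
}

idx_text_centered <- function(dm, text, cx, cy, scale = 2L) {
  idx_text(dm, text,
           cx - text_width_px(text, scale) / 2,
           cy - text_height_px(scale) / 2, scale)
}

# Draw `text` with its top-left at (x, y); returns the modified image.
draw_text <- function(img, text, x, y, scale = 2L, color = c(0, 0, 0)) {
  paint(img, idx_text(dim(img), text, x, y, scale), color)
}

# Draw text centered on (cx, cy).
draw_text_centered <- function(img, text, cx, cy, scale = 2L,
                               color = c(0, 0, 0)) {
  paint(img, idx_text_centered(dim(img), text, cx, cy, scale), color)
}
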