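# Internal helpers shared across modules.

# round-half-up at `digits` decimal places (display convention for percentages;
# base round() is banker's rounding and would turn 1.885 into 1.88)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# 1-based positions of any of `letters` in a sequence string (forward strand).
# Raw-byte comparison; fast enough for multi-megabase genomes.
letter_positions <- function(sequence, letters) {
  raw <- charToRaw(sequence)
  hit <- rep(FALSE, length(raw))
  for (l in letters) hit <- hit | raw == charToRaw(l)
  which(hit)
}

# Both-strand modifiable-base positions, as forward coordinates:
# cytosines live at forward C (on +) and forward G (C on -);
# adenines live at forward A (on +) and forward T (A on -).
modifiable_positions <- function(sequence, mod_type) {
  letters <- switch(mod_type,
    "4mC" = c("C", "G"),
    "6mA" = c("A", "T"),
    stop("unknown mod_type: ", mod_type)
  )
  letter_positions(sequence, letters)
}

# strand of the modifiable base at a forward coordinate, given its letter
strand_for_base <- function(base, mod_type) {
  fwd <- if (mod_type == "4mC") "C" else "A"
  ifelse(base == fwd, "+", "-")
}

stopifnot_scalar_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be a single non-NA string", call. = FALSE)
  }
}
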