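# Shared card designs and fixture helpers. All fixtures are generated
# in code at test time; nothing binary ships with the package.

fig1_categories <- function() {
  list(spot_category("Variety", values = c("A", "B", "C", "D")),
       spot_category("Flower", values = c("1", "2", "3")),
       spot_category("Plant", range_max = 99))
}

fig1_layout <- function(flower_diameter_mm = 20) {
  layout_card(fig1_categories(), flower_diameter_mm = flower_diameter_mm)
}

fig1_marks <- function() list(Variety = "B", Flower = "2", Plant = 37)

tiny_layout <- function() {
  layout_card(list(spot_category("Set", values = c("A", "B"))))
}

# A random but always-valid card design (used in property-style tests;
# call under a fixed seed).
random_layout <- function() {
  n_cat <- sample(1:3, 1L)
  cats <- lapply(seq_len(n_cat), function(i) {
    if (stats::runif(1) < 0.3)
      spot_category(paste0("Range", i), range_max = sample(c(9L, 99L), 1L))
    else
      spot_category(paste0("Cat", i),
                    values = sample(LETTERS, sample(2:6, 1L)))
  })
  flower <- if (stats::runif(1) < 0.5) 0 else sample(20:40, 1L)
  layout_card(cats, flower_diameter_mm = flower)
}

random_marks <- function(layout, mark_all = TRUE) {
  marks <- list()
  for (cs in layout$categories) {
    if (!mark_all && stats::runif(1) < 0.2) next
    marks[[cs$name]] <- if (cs$mode == "explicit") sample(cs$values, 1L)
    else sample.int(cs$range_max + 1L, 1L) - 1L
  }
  marks
}

# Fixture results reused across tests in one run (helpers persist for
# the whole test session).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A logical disc mask of radius r px centered in a square matrix.
disc_mask <- function(r, pad = 10L) {
  n <- 2L * r + 2L * pad + 1L
  xs <- rep(seq_len(n), times = n)
  ys <- rep(seq_len(n), each = n)
  cc <- (n + 1) / 2
  matrix((xs - cc)^2 + (ys - cc)^2 <= r^2, n, n)
}
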