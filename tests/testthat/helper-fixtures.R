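# shared fixture builders; everything is generated in code at test time

# points on an exact circle
circle_points <- function(n = 36, r = 0.1, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  tibble::tibble(x = cx + r * cos(th), y = cy + r * sin(th))
}

# a dense noiseless reference tree: spheroid crown over a tapered stem
reference_tree <- function(height = 20, dbh = 20, taper_k = 1,
                           crown_base = 10, crown_radius = 2,
                           crown_density = 500, stem_density = 500,
                           crown_shape = "spheroid", seed = 42) {
  m <- tree_model(height = height, dbh = dbh, taper_k = taper_k,
                  crown_shape = crown_shape, crown_base = crown_base,
                  crown_radius = crown_radius,
                  crown_density = crown_density,
                  stem_density = stem_density, noise_sd = 0)
  list(model = m,
       cloud = generate_tree(m, seed = seed, include_ground = FALSE))
}

# brute-force variable-window treetop detector (independent oracle)
vwf_brute_force <- function(chm, window_radius_fn, min_height = 2) {
  v <- chm$values
  d <- dim(v)
  hits <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    h0 <- v[i, j]
    if (is.na(h0) || h0 < min_height) next
    r <- window_radius_fn(h0) / chm$cell
    top <- TRUE
    first_tie <- TRUE
    for (i2 in seq_len(d[1])) for (j2 in seq_len(d[2])) {
      if ((i2 - i)^2 + (j2 - j)^2 > r^2) next
      h2 <- v[i2, j2]
      if (is.na(h2)) next
      if (h2 > h0) top <- FALSE
      if (h2 == h0 && (i2 < i || (i2 == i && j2 < j))) first_tie <- FALSE
    }
    if (top && first_tie) hits <- rbind(hits, c(i, j))
  }
  hits
}

# segmentation accuracy of a generated stand against its generator labels
stand_segmentation_check <- function(spec) {
  st <- generate_stand(spec)
  dtm <- build_dtm(st$cloud)
  pcn <- normalize_heights(st$cloud, dtm)
  chm <- rasterize_chm(pcn)
  tops <- detect_treetops(chm)
  segs <- watershed_crowns(chm, tops)
  asg <- assign_points(pcn, segs)
  tt <- st$truth
  nn <- FNN::get.knnx(cbind(tt$x, tt$y), cbind(tops$x, tops$y),
                      k = 1)$nn.index[, 1]
  map <- integer(nrow(tt))
  map[nn] <- tops$id
  accs <- vapply(seq_len(nrow(tt)), function(i) {
    sel <- st$cloud$tree == i & pcn$z >= 2
    mean(asg$tree[sel] == map[i])
  }, numeric(1))
  list(n_true = nrow(tt), n_tops = nrow(tops), accuracy = accs,
       cloud = st$cloud, assigned = asg)
}
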