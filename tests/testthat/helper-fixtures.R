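# Shared fixtures. Phantom generation is the expensive step, so presets used
# by several test files are generated once here (lazily, cached in the
# session).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

easy_phantom <- function(seed = 20260911L, noise_sd = 20)
  cached(sprintf("easy-%d-%g", seed, noise_sd),
         generate_phantom(default_test_spec("easy", noise_sd = noise_sd,
                                            seed = seed)))

easy_segmentation <- function(seed = 20260911L, noise_sd = 20)
  cached(sprintf("easyseg-%d-%g", seed, noise_sd),
         segment_lungs(easy_phantom(seed, noise_sd)$volume))

vessel_phantom <- function(seed = 20260911L, noise_sd = 20)
  cached(sprintf("vessel-%d-%g", seed, noise_sd),
         generate_phantom(default_test_spec("vessel-heavy",
                                            noise_sd = noise_sd,
                                            seed = seed)))

vessel_segmentation <- function(seed = 20260911L, noise_sd = 20)
  cached(sprintf("vesselseg-%d-%g", seed, noise_sd),
         segment_lungs(vessel_phantom(seed, noise_sd)$volume))

# a small uniform volume for plumbing tests
uniform_volume <- function(hu, dims = c(20, 24, 5), spacing = c(2.5, 1, 1)) {
  ct_volume(array(as.integer(hu), dim = dims), spacing = spacing,
            patient_id = "uniform")
}

# tiny random HU volume for round-trip tests
random_volume <- function(seed = 1, dims = c(8, 9, 4)) {
  with_seed(seed, ct_volume(
    array(sample(-1024:400, prod(dims), replace = TRUE), dim = dims),
    spacing = c(2.5, 0.7, 0.7), patient_id = sprintf("rand-%d", seed)))
}

lidc_fixture_path <- function()
  system.file("extdata", "lidc_sample.xml", package = "lungcand")

# printed confusion-count table rows for the GGO classifier comparison
# (two models, thresholds 0.1..0.9); tpr/precision/f as printed.
table2_rows <- function() {
  read.csv(text = 'model,threshold,tp,fn,fp,tn,tpr,precision,f
pretrained,0.1,262,31,43,257,0.894198,0.8590164,0.876254
pretrained,0.2,255,38,38,262,0.870307,0.8703072,0.870307
pretrained,0.3,255,38,33,267,0.870307,0.8854167,0.877797
pretrained,0.4,255,38,33,267,0.870307,0.8854167,0.877797
pretrained,0.5,253,40,31,269,0.863481,0.8908451,0.87695
pretrained,0.6,252,41,29,271,0.86007,0.8968,0.87805
pretrained,0.7,250,43,28,272,0.853242,0.8992806,0.875657
pretrained,0.8,246,47,25,275,0.83959,0.9077491,0.87234
pretrained,0.9,244,49,23,277,0.832765,0.9138577,0.871429
scratch,0.1,270,23,79,221,0.921502,0.773639,0.841121
scratch,0.2,269,24,72,228,0.918089,0.7888563,0.84858
scratch,0.3,267,26,66,234,0.911263,0.8018018,0.853035
scratch,0.4,265,28,63,237,0.904437,0.8079268,0.853462
scratch,0.5,263,30,59,241,0.89761,0.81677,0.85528
scratch,0.6,260,33,56,244,0.887372,0.8227848,0.853859
scratch,0.7,258,35,53,247,0.880546,0.829582,0.854305
scratch,0.8,256,37,51,249,0.87372,0.8338762,0.853333
scratch,0.9,250,43,46,254,0.853242,0.8445946,0.848896',
           colClasses = c(tpr = "character", precision = "character",
                          f = "character"))
}

# printed size-stratified detection table (threshold 0.5 nodule detector)
table1_rows <- function() {
  data.frame(tp = c(45, 55, 65, 77, 63), fn = c(7, 8, 1, 0, 0),
             sensitivity_pct = c(86.5, 87.3, 98.5, 100, 100))
}

# printed-precision comparison: |computed - printed| <= half ulp of printed
expect_printed <- function(computed, printed_chr) {
  printed <- as.numeric(printed_chr)
  d <- nchar(sub("^[^.]*\\.?", "", printed_chr))
  expect_lte(abs(computed - printed), 0.5 * 10^-d + 1e-12,
             label = sprintf("computed %.7f vs printed %s", computed,
                             printed_chr))
}
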