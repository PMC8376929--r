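# File formats

All coordinates are 0-based pixels, origin top-left, y increases downward;
boxes are half-open `[min, max)`.

## Images
- Input: 8/16-bit grayscale PNG or TIFF. Output: 8-bit PNG, one file per
  single knee, `<source_id>_<L|R>.png` after double-knee splitting.

## labels.csv (simulate / evaluate)
`knee_id, fl, fm, tl, tm, jsn_l, jsn_m, kl, oa, split`
Grades are integers (OARSI 0-3, KL 0-4, oa 0/1); `split` is
train/val/test (5:1:3 stratified by KL).

## keypoints.json (simulate / detector training)
Array of records: `{image, knee_id, box: [x1, y1, x2, y2],
keypoints: [[x, y] x 6]}`. Key-point order: lateral femoral margin,
medial femoral margin, lateral tibial margin, medial tibial margin,
lateral tibial spine, medial tibial spine.

## detections.csv (detect)
`knee_id, score, x1, y1, x2, y2, kx1, ky1, ..., kx6, ky6`.

## crop_manifest.csv (crop)
`knee_id, left, right, x1, y1, x2, y2` — patch file names and the origin
box of the refined region.

## preds.csv (predict)
`knee_id`, then per task `<task>` (argmax grade) and `<task>_prob`
(probability of the argmax). Tasks: kl, fl, fm, tl, tm, jsn_l, jsn_m, oa.

## report.json (evaluate)
`{n_samples, config_hash, metrics: [{task, top1, top_pm1,
kappa_quadratic, kappa_linear, kappa_none, mse}]}` plus one
`confusion_<task>.csv` per task (rows = true grade, cols = predicted).

## Configuration (YAML)
Sections `preprocess, detector, roi, grader, trainer, metrics, synth` and
a global `seed`; unknown keys are rejected, ranges validated. See
`load_config()`.
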