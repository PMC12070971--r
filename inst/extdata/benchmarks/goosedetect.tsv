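model	ap50_95	ap50	ap75
YOLOv5s	53.26	90.01	55.97
YOLOv8s	54.85	90.45	58.01
YOLOv9s	56.22	91.27	60.36
YOLOv10s	54.96	90.67	58.81
Mamba-YOLO-T	53.76	89.77	56.59
YOLOv11s	55.61	90.39	59.75
YOLO-SDD-s	56.47	91.71	60.68
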