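model	ap50_95	ap50	ap75
YOLOv5s	58.87	95.62	64.84
YOLOv8s	60.72	97.38	68.21
YOLOv9s	61.97	97.19	70.95
YOLOv10s	61.45	97.57	69.81
Mamba-YOLO-T	59.58	96.93	67.80
YOLOv11s	60.68	97.26	69.28
YOLO-SDD-s	62.35	97.78	71.09
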