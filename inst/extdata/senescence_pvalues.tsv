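circ_id	cell_type	p	expressed
circAFF1	astrocytes	0.040	TRUE
circASAP1	astrocytes	0.878	TRUE
circATP6V0A1	astrocytes	0.229	TRUE
circCDYL	astrocytes	0.001	TRUE
circEP300	astrocytes	0.329	TRUE
circFNDC3B	astrocytes	0.059	TRUE
circFOXO3	astrocytes	0.646	TRUE
circMETTL3	astrocytes	0.180	TRUE
circMIB1	astrocytes	0.008	TRUE
circPLEKHM1	astrocytes	0.306	TRUE
circXPO7	astrocytes	0.987	TRUE
circZC3H18	astrocytes	0.346	TRUE
circAFF1	cardiomyocytes	0.357	TRUE
circASAP1	cardiomyocytes	0.643	TRUE
circATP6V0A1	cardiomyocytes	0.249	TRUE
circCDYL	cardiomyocytes	0.855	TRUE
circEP300	cardiomyocytes	0.596	TRUE
circFNDC3B	cardiomyocytes	0.139	TRUE
circFOXO3	cardiomyocytes	0.015	TRUE
circMETTL3	cardiomyocytes	0.186	TRUE
circMIB1	cardiomyocytes	0.129	TRUE
circPLEKHM1	cardiomyocytes	0.983	TRUE
circXPO7	cardiomyocytes	0.227	TRUE
circZC3H18	cardiomyocytes	0.862	TRUE
circAFF1	endothelial	0.548	TRUE
circASAP1	endothelial	0.467	TRUE
circATP6V0A1	endothelial	0.821	TRUE
circCDYL	endothelial	0.942	TRUE
circEP300	endothelial	0.128	TRUE
circFNDC3B	endothelial	0.080	TRUE
circFOXO3	endothelial	0.275	TRUE
circMETTL3	endothelial	0.072	TRUE
circMIB1	endothelial	0.640	TRUE
circPLEKHM1	endothelial	0.380	TRUE
circXPO7	endothelial	0.620	TRUE
circZC3H18	endothelial	0.047	TRUE
circAFF1	fibroblasts	0.003	TRUE
circASAP1	fibroblasts	0.196	TRUE
circATP6V0A1	fibroblasts	0.375	TRUE
circCDYL	fibroblasts	0.640	TRUE
circEP300	fibroblasts	0.023	TRUE
circFNDC3B	fibroblasts	0.182	TRUE
circFOXO3	fibroblasts	0.025	TRUE
circMETTL3	fibroblasts	0.030	TRUE
circMIB1	fibroblasts	0.072	TRUE
circPLEKHM1	fibroblasts	0.716	TRUE
circXPO7	fibroblasts	0.645	TRUE
circZC3H18	fibroblasts	0.432	TRUE
circBCL11B	astrocytes	NA	FALSE
circDEF6	astrocytes	NA	FALSE
circITGAX	astrocytes	NA	FALSE
circBCL11B	cardiomyocytes	NA	FALSE
circDEF6	cardiomyocytes	NA	FALSE
circITGAX	cardiomyocytes	NA	FALSE
circBCL11B	endothelial	NA	FALSE
circDEF6	endothelial	NA	FALSE
circITGAX	endothelial	NA	FALSE
circBCL11B	fibroblasts	NA	FALSE
circDEF6	fibroblasts	NA	FALSE
circITGAX	fibroblasts	NA	FALSE
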