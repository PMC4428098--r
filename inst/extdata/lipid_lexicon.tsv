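term	generic	class	kind
Gemfibrozil	gemfibrozil	fibrate	name
Lopid	gemfibrozil	fibrate	name
Fenofibrate	fenofibrate	fibrate	name
Antara	fenofibrate	fibrate	name
Lofibra	fenofibrate	fibrate	name
Tricor	fenofibrate	fibrate	name
Triglide	fenofibrate	fibrate	name
Clofibrate	clofibrate	fibrate	name
Atromid-S	clofibrate	fibrate	name
Cholestyramine	cholestyramine	resin	name
Questran	cholestyramine	resin	name
Questran Light	cholestyramine	resin	name
Prevalite	cholestyramine	resin	name
Locholest	cholestyramine	resin	name
Locholest Light	cholestyramine	resin	name
Colestipol	colestipol	resin	name
Colestid	colestipol	resin	name
Colesevelam	colesevelam	resin	name
Colesevelam Hcl	colesevelam	resin	name
WelChol	colesevelam	resin	name
Atorvastatin	atorvastatin	statin	name
Lipitor	atorvastatin	statin	name
Fluvastatin	fluvastatin	statin	name
Lescol	fluvastatin	statin	name
Lovastatin	lovastatin	statin	name
Mevacor	lovastatin	statin	name
Altoprev	lovastatin	statin	name
Pravastatin	pravastatin	statin	name
Pravachol	pravastatin	statin	name
Rosuvastatin	rosuvastatin	statin	name
Rosuvastatin Calcium	rosuvastatin	statin	name
Crestor	rosuvastatin	statin	name
Simvastatin	simvastatin	statin	name
Zocor	simvastatin	statin	name
Advicor	lovastatin-niacin	combination	name
Caduet	atorvastatin-amlodipine	combination	name
Vytorin	simvastatin-ezetimibe	combination	name
Ezetimibe	ezetimibe	cholesterol-absorption-inhibitor	name
Zetia	ezetimibe	cholesterol-absorption-inhibitor	name
Niacin	niacin	niacin	name
Fibrate	fibrate	fibrate	class
Fibrates	fibrate	fibrate	class
Statin	statin	statin	class
Statins	statin	statin	class
Resins	resin	resin	class
Bile acid resin	resin	resin	class
Cholesterol absorption inhibitor	cholesterol-absorption-inhibitor	cholesterol-absorption-inhibitor	class
HMG CoA reductase inhibitor	statin	statin	class
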